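---
title: "Scoring mutation-drug sensitivity associations in cell-line panels"
author: "PharmacoMut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mutation-drug sensitivity associations in cell-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(PharmacoMut))
```

## The problem

Large cell-line screens report drug activity as GI50 — minus the log10 of
the molar concentration inhibiting 50% of growth — for tens of thousands
of compounds over a panel of cancer cell lines, while sequencing projects
catalogue each line's mutations. PharmacoMut links the two: given a
mutation-defined group of cell lines it ranks compounds by selective
activity on that group (*gene to drug*), and given a compound it ranks
mutations by their association with sensitivity or resistance
(*drug to gene*).

## From GI50 to response calls

For each compound the GI50 values are transformed back to molar IC50
(`IC50 = 10^-GI50`) and divided by the compound's mean IC50 across its
*tested* cell lines; the ratio is analysed on the log2 scale. This makes
compounds of very different absolute potency comparable: a normalized
log2 IC50 of −3 means the line is 8-fold more sensitive than the panel
average for that compound, and the linear-scale normalized values of
every compound average to exactly 1.

Each cell line then receives a ternary call per compound. Let
$\mu_j, \sigma_j$ be the mean and sample standard deviation of the
normalized log2 IC50 of all tested compounds in cell line $j$. A tested
entry with value $x$ is a **good response** when

$$x < \mu_j - k\,\sigma_j, \qquad k = 2 \text{ by default},$$

and a **bad response** otherwise. The phrase "lower than two standard
deviations of the distribution" admits two readings — a cut at
$-k\sigma_j$ from zero or from the column's own mean. Normalization
guarantees a unit mean per *compound* (row), not per *cell line*
(column), so only the mean-relative form is coherent for an arbitrary
column; it is the default, with `fixedZeroMean = TRUE` exposing the
zero-anchored alternative. In practice column means sit near zero and the
two agree closely. With a Gaussian column the expected good-call rate is
$\Phi(-2) \approx 2.3\%$, which the test suite verifies empirically on a
10,000-compound simulated column.

Two degenerate situations are handled explicitly: a cell line with zero
spread yields no good calls (nothing is *strictly* below its mean), and
cell lines with fewer than 3 tested compounds, or compounds tested on
fewer than `minTested = 10` lines, are excluded with a logged reason —
the 2-SD rule is meaningless on a handful of points. The sample
(n−1) standard deviation is used throughout.

## The enrichment score and test

For a case/control split of the tested cell lines, each compound yields a
2×2 table of good/bad responses. The ranking score is

$$S \;=\; \frac{\text{good in cases}}{\text{cases}} \times
          \frac{\text{bad in controls}}{\text{controls}} \;\in\; [0, 1],$$

reaching 1 only at perfect separation. Significance is a one-tailed
Fisher exact test for enrichment of good responses in cases — the
upper-tail hypergeometric probability of observing at least the attained
number of good case responses given the table margins (computed with
`phyper`; the test suite checks it against brute-force enumeration of
every 2×2 table with margins ≤ 15 to 10⁻¹²). The one-sided form matches
the directional question being asked; no multiple-testing correction is
applied to the headline ranking, but a Benjamini–Hochberg `q_value`
column is emitted alongside for modern use.

In the *gene-to-drug* direction, cases are the harmonized cell lines
carrying the queried mutation set (all of, or any of, several genes /
dbSNP ids; tissue and variant-classification filters apply to both sides
of the split) and controls are all other lines. Compounds need at least
`minCase = 2` tested cases and `minCtrl = 5` tested controls to be
scored; these guards are this package's own additions for sparse
screening data. A compound is flagged significant at `p < 0.05` and
`score > 0.3`, both configurable.

In the *drug-to-gene* direction the compound's own good- and
bad-response lines form the two groups, and for each mutation key
(gene + variant classification + dbSNP id when present) carriage plays
the role of the "good" outcome: the sensitivity statistic asks whether
carriers are enriched among good responders. Resistance is the mirrored
test with the groups swapped — the minimal construction consistent with
a single directional score, and exactly symmetric (swapping the groups
exchanges the two statistics). Identical variant calls for the same line
are deduplicated before counting carriers, but the raw call count is
kept as the volcano bubble size. Volcano flags use the same
`p < 0.05` / `score > 0.3` thresholds and are mutually exclusive (the
smaller p wins in the unlikely event both directions fire).

Drug-family enrichment asks whether a family is over-represented among
compounds with `score > 0.6`, again with a one-tailed Fisher test on the
(in family) × (passing) table. Because family annotation is typically
sparse, the background defaults to annotated compounds only
(`background = "all"` includes the rest). An alternative reading of
family ranking — order families by their best member's p — is available
for exploration but the family-level contingency test is the default,
being an actual test rather than a ranking heuristic.

## Identifier harmonization

Response and mutation sources name cell lines differently, mostly in
punctuation and case (`MDA-MB-231` vs `MDAMB231`). Both sides are
reduced to case-folded alphanumeric keys, an optional user alias map
handles the remainder, and both objects are restricted to the
intersection with the mutation side relabelled to the response spelling.
The operation is idempotent and reports dropped names from each side.
How any particular portal matched its sources is not reconstructable in
general, which is why the alias map is externalized. Response calls are
computed on the harmonized matrix by default; computing them on the full
matrix first is a one-flag change in the pipeline functions.

## The synthetic panel generator

`generatePanel()` draws GI50 as a per-compound baseline
(Gaussian, log10 scale) plus independent Gaussian noise, i.e. log-normal
IC50 — the standard model for potency measurements. A planted effect
multiplies the IC50 of its carrier lines by `2^effect_log2`
(equivalently shifts GI50 by `-effect_log2·log10(2)`; −3 log2 units ≈
+0.903 GI50 units), and the carriers are written into the mutation
table alongside independent Bernoulli background mutations with tissue
labels in contiguous blocks. All draws come from one Mersenne-Twister
stream seeded from the spec, so panels and fixture bundles are
byte-reproducible.

The defaults are the reference conditions used by the test suite and the
acceptance script: 2,000 compounds × 60 cell lines, 6 tissues, 10%
missingness, baseline GI50 ~ N(5, 0.5²) (i.e. IC50 centred near 10 µM),
noise 0.2 log2 units, a 50-gene background panel at 5% per-gene-per-line
prevalence, eight families of 25 compounds, and one sensitizing lesion
of −3 log2 units in 8 carriers. The panel size keeps a hundred
replicates comfortably cheap while leaving the planted compound's
signal realistic rather than trivial. The spec's field list leaves the
background panel size open; 50 genes gives each line about 2–3
background mutations, enough to exercise filters and type-I behaviour.

What the generator does *not* emulate: correlated compound activities
(real screens contain families of near-identical molecules), mutational
signatures or gene-length effects, tissue-specific response structure,
and non-random missingness. Passing the planted-recovery and
calibration tests therefore demonstrates correctness of the statistical
machinery under its stated model, not performance on real screening
data.

A note on lines without calls: the mutation table's universe defaults to
lines observed in the table, so at the default mutation rate a few
percent of lines carry no record and drop out at harmonization — as they
would with a real catalogue. An explicit universe file
(`readMutationTable(..., universeFile =)`) retains them.

## Numerical and design choices

* Ordering of every result table is total — p ascending, score
  descending, identifier ascending — so repeated runs are
  byte-identical; TSV p-values are fixed at three significant digits in
  scientific notation, JSON keeps full precision.
* Counts and scores come only from tested entries; untested cells never
  enter a mean, SD, or contingency table.
* The upper-tail p is clamped to 1 against floating-point overshoot.
* CLI exit codes: 0 success, 2 input/validation error, 3 legitimately
  empty result (e.g. a query matching no case line); no output file is
  written on failure.

## A worked example

```{r example, message = FALSE}
spec <- PanelSpec(nCompounds = 500, nCellLines = 60,
                  plantedEffects = data.frame(compound_id = "NSC-00250",
                                              gene = "MUT1",
                                              effect_log2 = -3,
                                              n_carriers = 8),
                  seed = 42)
panel <- generatePanel(spec)
h <- harmonizeCellLines(panel$response, panel$mutations)
calls <- callResponses(normalizeResponse(h$response))
split <- selectCaseLines(h$mutations, MutationQuery(genes = "MUT1"))
res <- geneToDrug(calls, split, panel$annotations)
head(res[, c("compound_id", "n_case_good", "n_case_bad",
             "n_ctrl_good", "n_ctrl_bad", "score", "p_value")], 3)

volcano <- drugToGene(calls, "NSC-00250", h$mutations)
head(volcano[, c("gene", "score_sens", "p_sens", "sensitivity")], 3)
```

The planted compound tops the gene-to-drug ranking and the planted gene
is the only sensitivity-flagged mutation key for that compound.

## Limitations

The score is a product of two fractions and ignores effect magnitude
beyond the binary call; a compound mildly but consistently more active
in cases can outrank one with a huge effect in a single line, which is
the intended behaviour of a call-based enrichment but differs from
continuous-response methods. Fisher's exact test is conservative at the
small group sizes typical of mutation queries (the null panels in the
test suite show compound-level false-positive fractions well below the
nominal 5%), so raw p-values near the threshold should be read as
ranking devices rather than calibrated error rates — one reason the
output also carries q-values.
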