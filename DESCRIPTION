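Package: PharmacoMut
Title: Bidirectional Mutation-Drug Sensitivity Association for Cancer
    Cell-Line Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links large-scale drug-response screens (GI50 matrices over
    cancer cell-line panels) to cell-line mutation catalogues. Converts
    GI50 to normalized log2 IC50, calls good/bad responses per cell line
    with a mean minus 2 SD rule, and computes bidirectional case/control
    enrichment: compounds selectively active on mutation-defined groups
    of cell lines (gene to drug) and mutations associated with
    sensitivity or resistance to a given compound (drug to gene), each
    with an enrichment score and a one-tailed Fisher exact test, plus
    drug-family set enrichment and volcano-style significance calls. A
    seeded synthetic-panel generator with planted sensitizing and
    resistance lesions supports end-to-end testing without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Pharmacogenomics, Software, StatisticalMethod, CellBasedAssays
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
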