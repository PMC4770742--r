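.VARIANT_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation",
                      "Frame_Shift_Del", "Splice_Site", "Silent")
.VARIANT_CLASS_PROBS <- c(0.55, 0.15, 0.1, 0.05, 0.15)

#' Construct a PanelSpec
#'
#' Defaults describe the reference simulation panel used throughout the
#' package's tests: 2,000 compounds on 60 cell lines over 6 tissues,
#' 10\% sporadic missingness, log-normal IC50 with per-compound location
#' (GI50 baseline mean 5, SD 0.5 log10 units), Gaussian measurement
#' noise of 0.2 log2 units, a 50-gene background mutation catalogue at
#' 5\% per-gene-per-line prevalence, eight drug families of 25 members,
#' and one planted sensitizing lesion: compound `NSC-01000` is 3 log2
#' units (8-fold) more potent on the 8 carriers of gene `MUT1`.
#'
#' @param nCompounds,nCellLines,nTissues panel dimensions.
#' @param missingRate probability an entry is untested.
#' @param baselineGI50Mean,baselineGI50SD compound GI50 location
#'   distribution (log10 units).
#' @param noiseSD per-entry noise on the log2 IC50 scale.
#' @param plantedEffects data.frame (`compound_id`, `gene`,
#'   `effect_log2`, `n_carriers`); negative effects sensitize (IC50 is
#'   multiplied by `2^effect_log2` in carrier lines). Use a 0-row frame
#'   for a null panel.
#' @param mutationRate background per-gene-per-line probability.
#' @param nBackgroundGenes background gene-panel size.
#' @param families named integer vector, family label -> member count.
#' @param seed RNG seed.
#' @return a [PanelSpec-class].
#' @export
PanelSpec <- function(nCompounds = 2000L, nCellLines = 60L, nTissues = 6L,
                      missingRate = 0.1, baselineGI50Mean = 5,
                      baselineGI50SD = 0.5, noiseSD = 0.2,
                      plantedEffects = data.frame(
                          compound_id = "NSC-01000", gene = "MUT1",
                          effect_log2 = -3, n_carriers = 8L,
                          stringsAsFactors = FALSE),
                      mutationRate = 0.05, nBackgroundGenes = 50L,
                      families = stats::setNames(rep(25L, 8L),
                                                 sprintf("FAM%d", 1:8)),
                      seed = 1L) {
    new("PanelSpec", nCompounds = as.integer(nCompounds),
        nCellLines = as.integer(nCellLines), nTissues = as.integer(nTissues),
        missingRate = missingRate, baselineGI50Mean = baselineGI50Mean,
        baselineGI50SD = baselineGI50SD, noiseSD = noiseSD,
        plantedEffects = plantedEffects, mutationRate = mutationRate,
        nBackgroundGenes = as.integer(nBackgroundGenes),
        families = stats::setNames(as.integer(families), names(families)),
        seed = as.integer(seed))
}

#' Generate a synthetic screening panel with known planted structure
#'
#' Draws a GI50 matrix as per-compound baseline (Gaussian in log10
#' units) plus independent Gaussian noise (`noiseSD` log2 units,
#' converted internally), multiplies the IC50 of each planted effect's
#' carrier lines by `2^effect_log2` (equivalently shifts their GI50 by
#' `-effect_log2 * log10(2)`), applies uniform missingness, and builds a
#' mutation catalogue of the planted carrier lesions plus independent
#' Bernoulli background mutations with contiguous tissue blocks. Fully
#' reproducible from the spec's seed (Mersenne-Twister / inversion).
#'
#' @param spec a [PanelSpec-class].
#' @return a list with elements `response`
#'   ([ResponseExperiment-class]), `mutations` ([MutationTable-class]),
#'   `annotations` (data.frame) and `truth` (data.frame of planted
#'   effects with their carrier lines).
#' @export
generatePanel <- function(spec) {
    validObject(spec)
    set.seed(spec@seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    n <- spec@nCompounds
    m <- spec@nCellLines
    ids <- sprintf("NSC-%05d", seq_len(n))
    lines <- sprintf("CL-%03d", seq_len(m))
    tissueOf <- sprintf("TISSUE%02d",
                        ceiling(seq_len(m) / ceiling(m / spec@nTissues)))
    pe <- spec@plantedEffects
    if (nrow(pe) && !all(pe$compound_id %in% ids))
        .inputError("planted compound(s) outside the panel: %s",
                    paste(setdiff(pe$compound_id, ids), collapse = ", "))

    baseline <- stats::rnorm(n, spec@baselineGI50Mean, spec@baselineGI50SD)
    noise <- matrix(stats::rnorm(n * m, 0, spec@noiseSD * log10(2)), n, m)
    g <- baseline + noise
    dimnames(g) <- list(ids, lines)

    truth <- NULL
    plantedRecords <- NULL
    if (nrow(pe)) {
        for (i in seq_len(nrow(pe))) {
            carriers <- sample(lines, pe$n_carriers[i])
            g[pe$compound_id[i], carriers] <-
                g[pe$compound_id[i], carriers] - pe$effect_log2[i] * log10(2)
            truth <- rbind(truth, data.frame(
                compound_id = pe$compound_id[i], gene = pe$gene[i],
                effect_log2 = pe$effect_log2[i], n_carriers = pe$n_carriers[i],
                carriers = paste(sort(carriers), collapse = ";"),
                stringsAsFactors = FALSE))
            plantedRecords <- rbind(plantedRecords, data.frame(
                cell_line = sort(carriers), tissue = NA_character_,
                gene = pe$gene[i], variant_classification = "Missense_Mutation",
                mutation_type = "SNP", chromosome = NA_character_,
                position = NA_integer_, dbsnp_id = NA_character_,
                stringsAsFactors = FALSE))
        }
    } else {
        truth <- data.frame(compound_id = character(0), gene = character(0),
                            effect_log2 = numeric(0), n_carriers = integer(0),
                            carriers = character(0), stringsAsFactors = FALSE)
    }

    tested <- matrix(stats::runif(n * m) >= spec@missingRate, n, m,
                     dimnames = dimnames(g))

    nbg <- spec@nBackgroundGenes
    bgGenes <- sprintf("BG%03d", seq_len(nbg))
    hit <- which(matrix(stats::runif(nbg * m) < spec@mutationRate, nbg, m),
                 arr.ind = TRUE)
    bgRecords <- if (nrow(hit)) data.frame(
        cell_line = lines[hit[, 2L]], tissue = NA_character_,
        gene = bgGenes[hit[, 1L]],
        variant_classification = sample(.VARIANT_CLASSES, nrow(hit),
                                        replace = TRUE,
                                        prob = .VARIANT_CLASS_PROBS),
        mutation_type = "SNP",
        chromosome = as.character(sample(1:22, nrow(hit), replace = TRUE)),
        position = sample.int(2e8L, nrow(hit), replace = TRUE),
        dbsnp_id = NA_character_, stringsAsFactors = FALSE) else NULL
    if (!is.null(bgRecords)) {
        tagged <- stats::runif(nrow(bgRecords)) < 0.3
        bgRecords$dbsnp_id[tagged] <- sprintf("rs%07d",
            sample.int(9999999L, sum(tagged)))
    }
    rec <- rbind(plantedRecords, bgRecords)
    if (is.null(rec) || !nrow(rec))
        .emptyError("spec produced an empty mutation table; raise mutationRate or plant an effect")
    rec$tissue <- tissueOf[match(rec$cell_line, lines)]
    rec <- rec[order(rec$cell_line, rec$gene, rec$position), , drop = FALSE]
    rownames(rec) <- NULL

    fam <- rep(NA_character_, n)
    pos <- 1L
    for (j in seq_along(spec@families)) {
        cnt <- min(spec@families[[j]], n - pos + 1L)
        if (cnt <= 0L) break
        fam[pos:(pos + cnt - 1L)] <- names(spec@families)[j]
        pos <- pos + cnt
    }
    annotations <- data.frame(
        compound_id = ids, name = paste0("cpd-", sub("^NSC-", "", ids)),
        family = fam, mechanism = NA_character_,
        fda_status = NA_character_, stringsAsFactors = FALSE)

    list(response = ResponseExperiment(g, tested),
         mutations = MutationTable(rec, cellLineUniverse = unique(rec$cell_line)),
         annotations = annotations, truth = truth)
}

.panelSpecToList <- function(spec) {
    list(n_compounds = spec@nCompounds, n_cell_lines = spec@nCellLines,
         n_tissues = spec@nTissues, missing_rate = spec@missingRate,
         baseline_gi50_mean = spec@baselineGI50Mean,
         baseline_gi50_sd = spec@baselineGI50SD, noise_sd = spec@noiseSD,
         planted_effects = if (nrow(spec@plantedEffects))
             lapply(seq_len(nrow(spec@plantedEffects)), function(i)
                 as.list(spec@plantedEffects[i, ])) else list(),
         mutation_rate = spec@mutationRate,
         n_background_genes = spec@nBackgroundGenes,
         families = as.list(spec@families), seed = spec@seed)
}

#' Read a PanelSpec from a YAML configuration
#'
#' Accepts the file written by [writeFixtureBundle()]; omitted fields
#' fall back to the [PanelSpec()] defaults.
#'
#' @param path path to a YAML panel spec.
#' @return a [PanelSpec-class].
#' @export
readPanelSpec <- function(path) {
    y <- yaml::read_yaml(path)
    args <- list()
    take <- function(yname, aname) {
        if (!is.null(y[[yname]])) args[[aname]] <<- y[[yname]]
    }
    take("n_compounds", "nCompounds"); take("n_cell_lines", "nCellLines")
    take("n_tissues", "nTissues"); take("missing_rate", "missingRate")
    take("baseline_gi50_mean", "baselineGI50Mean")
    take("baseline_gi50_sd", "baselineGI50SD"); take("noise_sd", "noiseSD")
    take("mutation_rate", "mutationRate")
    take("n_background_genes", "nBackgroundGenes")
    take("seed", "seed")
    if (!is.null(y$planted_effects)) {
        pe <- y$planted_effects
        args$plantedEffects <- if (length(pe))
            do.call(rbind, lapply(pe, function(e)
                data.frame(compound_id = e$compound_id, gene = e$gene,
                           effect_log2 = e$effect_log2,
                           n_carriers = as.integer(e$n_carriers),
                           stringsAsFactors = FALSE)))
        else data.frame(compound_id = character(0), gene = character(0),
                        effect_log2 = numeric(0), n_carriers = integer(0),
                        stringsAsFactors = FALSE)
    }
    if (!is.null(y$families))
        args$families <- stats::setNames(as.integer(unlist(y$families)),
                                         names(y$families))
    do.call(PanelSpec, args)
}

#' Write a complete fixture bundle for a synthetic panel
#'
#' Emits the three analysis inputs (response matrix, MAF-style mutation
#' table, drug annotations), the planted-effect truth table, and the
#' panel spec as YAML. Regeneration from the same spec overwrites the
#' files identically.
#'
#' @param spec a [PanelSpec-class].
#' @param outDir output directory (created if needed).
#' @return named character vector of the five file paths, invisibly.
#' @export
writeFixtureBundle <- function(spec, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir))
        .inputError("cannot create output directory '%s'", outDir)
    panel <- generatePanel(spec)
    paths <- c(response = file.path(outDir, "response.tsv"),
               mutations = file.path(outDir, "mutations.tsv"),
               annotations = file.path(outDir, "annotations.tsv"),
               truth = file.path(outDir, "truth.tsv"),
               spec = file.path(outDir, "panel_spec.yaml"))
    writeResponseMatrix(panel$response, paths[["response"]])
    rec <- as.data.frame(mutationRecords(panel$mutations))
    names(rec) <- unname(.DEFAULT_MUTATION_MAP[names(rec)])
    utils::write.table(rec, paths[["mutations"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    utils::write.table(panel$annotations, paths[["annotations"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE,
                       na = "")
    utils::write.table(panel$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    yaml::write_yaml(.panelSpecToList(spec), paths[["spec"]])
    invisible(paths)
}
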