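#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

.checkDimnames <- function(object) {
    msgs <- character(0)
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msgs <- c(msgs, "compound (row) and cell-line (column) names are required")
    else {
        if (anyDuplicated(rownames(object)))
            msgs <- c(msgs, "duplicated compound identifiers")
        if (anyDuplicated(colnames(object)))
            msgs <- c(msgs, "duplicated cell-line names")
    }
    msgs
}

.checkMaskedAssay <- function(object, value_assay) {
    msgs <- character(0)
    if (!all(c(value_assay, "tested") %in% assayNames(object)))
        return(sprintf("assays '%s' and 'tested' are required", value_assay))
    tst <- assay(object, "tested")
    if (!is.logical(tst))
        msgs <- c(msgs, "'tested' assay must be logical")
    val <- assay(object, value_assay)
    if (!is.numeric(val))
        msgs <- c(msgs, sprintf("'%s' assay must be numeric", value_assay))
    else if (is.logical(tst) && any(!is.finite(val[tst])))
        msgs <- c(msgs, sprintf("non-finite '%s' value marked as tested", value_assay))
    msgs
}

#' ResponseExperiment: a compound x cell-line GI50 screen
#'
#' A [SummarizedExperiment::SummarizedExperiment] with rows = compounds,
#' columns = cell lines, and two assays: `gi50` (minus log10 molar IC50)
#' and `tested` (logical mask; `FALSE` marks untested entries, which are
#' excluded from every downstream statistic).
#'
#' @aliases ResponseExperiment-class
#' @seealso [readResponseMatrix()], [normalizeResponse()]
#' @export
setClass("ResponseExperiment", contains = "SummarizedExperiment")

setValidity("ResponseExperiment", function(object) {
    msgs <- c(.checkDimnames(object), .checkMaskedAssay(object, "gi50"))
    if (length(msgs)) msgs else TRUE
})

#' NormalizedResponse: per-compound normalized log2 IC50
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the
#' `log2NormIC50` assay (log2 of IC50 divided by the compound's mean IC50
#' over its tested cell lines) and the `tested` mask. For every compound
#' the mean of `2^log2NormIC50` over tested entries is 1 by construction.
#'
#' @aliases NormalizedResponse-class
#' @seealso [normalizeResponse()], [callResponses()]
#' @export
setClass("NormalizedResponse", contains = "SummarizedExperiment")

setValidity("NormalizedResponse", function(object) {
    msgs <- c(.checkDimnames(object), .checkMaskedAssay(object, "log2NormIC50"))
    if (length(msgs)) msgs else TRUE
})

#' ResponseCalls: ternary good/bad/untested response calls
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single character
#' assay `call` over `{"good", "bad", NA}` (`NA` = untested) and per
#' cell-line summaries of the normalized log2 IC50 distribution in
#' `colData`: `lineMean`, `lineSD` and `nTested`. An entry is `"good"`
#' when its normalized log2 IC50 falls below `lineMean - k * lineSD` of
#' its cell line, `"bad"` otherwise.
#'
#' @aliases ResponseCalls-class
#' @seealso [callResponses()], [geneToDrug()], [drugToGene()]
#' @export
setClass("ResponseCalls", contains = "SummarizedExperiment")

setValidity("ResponseCalls", function(object) {
    msgs <- .checkDimnames(object)
    if (!("call" %in% assayNames(object)))
        msgs <- c(msgs, "assay 'call' is required")
    else {
        cl <- assay(object, "call")
        bad <- setdiff(unique(as.vector(cl)), c("good", "bad", NA))
        if (length(bad))
            msgs <- c(msgs, sprintf("invalid call values: %s",
                                    paste(bad, collapse = ", ")))
    }
    need <- c("lineMean", "lineSD", "nTested")
    if (!all(need %in% colnames(colData(object))))
        msgs <- c(msgs, "colData must carry lineMean, lineSD, nTested")
    if (length(msgs)) msgs else TRUE
})

#' MutationTable: long-format variant calls over a cell-line panel
#'
#' Holds one row per variant call (cell line, tissue, gene, variant
#' classification, mutation type, chromosome, position, dbSNP id) plus the
#' universe of sequenced cell lines, which may include lines with zero
#' calls.
#'
#' @slot records a [S4Vectors::DataFrame] of variant calls.
#' @slot cellLineUniverse character vector of all sequenced cell lines.
#' @aliases MutationTable-class
#' @seealso [readMutationTable()], [selectCaseLines()]
#' @export
setClass("MutationTable",
    representation(records = "DataFrame", cellLineUniverse = "character"))

.MUTATION_FIELDS <- c("cell_line", "tissue", "gene", "variant_classification",
                      "mutation_type", "chromosome", "position", "dbsnp_id")

setValidity("MutationTable", function(object) {
    msgs <- character(0)
    rec <- object@records
    miss <- setdiff(.MUTATION_FIELDS, colnames(rec))
    if (length(miss))
        return(sprintf("records lack columns: %s", paste(miss, collapse = ", ")))
    if (nrow(rec)) {
        if (any(is.na(rec$cell_line) | rec$cell_line == ""))
            msgs <- c(msgs, "empty cell_line in records")
        if (any(is.na(rec$gene) | rec$gene == ""))
            msgs <- c(msgs, "empty gene in records")
        ids <- rec$dbsnp_id[!is.na(rec$dbsnp_id)]
        if (length(ids) && !all(grepl("^rs", ids)))
            msgs <- c(msgs, "dbsnp_id values must start with 'rs'")
        if (!all(rec$cell_line %in% object@cellLineUniverse))
            msgs <- c(msgs, "record cell lines outside cellLineUniverse")
    }
    if (anyDuplicated(object@cellLineUniverse))
        msgs <- c(msgs, "duplicated cell lines in universe")
    if (length(msgs)) msgs else TRUE
})

#' MutationQuery: a gene/SNP selection with optional filters
#'
#' Describes the mutation-defined case group for a gene-to-drug analysis:
#' gene symbols and/or dbSNP identifiers, how multiple entities combine
#' (`"all_of"` requires a line to carry every queried entity, `"any_of"`
#' at least one), and optional tissue / variant-classification filters.
#' Filters of length zero are inactive.
#'
#' @aliases MutationQuery-class
#' @seealso [selectCaseLines()]
#' @export
setClass("MutationQuery",
    representation(genes = "character", dbsnpIds = "character",
                   tissues = "character", variantClasses = "character",
                   combineMode = "character"),
    prototype(genes = character(0), dbsnpIds = character(0),
              tissues = character(0), variantClasses = character(0),
              combineMode = "all_of"))

setValidity("MutationQuery", function(object) {
    msgs <- character(0)
    if (!length(object@genes) && !length(object@dbsnpIds))
        msgs <- c(msgs, "at least one gene or dbSNP id is required")
    if (length(object@combineMode) != 1L ||
        !object@combineMode %in% c("all_of", "any_of"))
        msgs <- c(msgs, "combineMode must be 'all_of' or 'any_of'")
    if (length(msgs)) msgs else TRUE
})

#' CaseControlSplit: disjoint case and control cell-line sets
#'
#' @aliases CaseControlSplit-class
#' @seealso [selectCaseLines()], [geneToDrug()]
#' @export
setClass("CaseControlSplit",
    representation(caseLines = "character", controlLines = "character"))

setValidity("CaseControlSplit", function(object) {
    if (length(intersect(object@caseLines, object@controlLines)))
        "case and control cell lines must be disjoint"
    else TRUE
})

#' PanelSpec: parameters of a synthetic screening panel
#'
#' Describes a seeded synthetic panel: log-normal IC50 per compound with
#' Gaussian cell-line noise on the log scale, uniform sporadic
#' missingness, a background mutation catalogue with contiguous tissue
#' blocks, planted sensitizing / resistance lesions of configurable
#' effect size, and drug-family labels for set enrichment.
#'
#' @slot nCompounds,nCellLines,nTissues panel dimensions.
#' @slot missingRate probability an entry is untested.
#' @slot baselineGI50Mean,baselineGI50SD per-compound GI50 location
#'   distribution (log10 units).
#' @slot noiseSD per-entry Gaussian noise on the log2 IC50 scale.
#' @slot plantedEffects data.frame with columns `compound_id`, `gene`,
#'   `effect_log2` (negative = sensitizing, positive = resistance) and
#'   `n_carriers`.
#' @slot mutationRate per-gene-per-line background mutation probability.
#' @slot nBackgroundGenes size of the background gene panel.
#' @slot families named integer vector, family label -> member count.
#' @slot seed integer RNG seed (Mersenne-Twister).
#' @aliases PanelSpec-class
#' @seealso [generatePanel()], [writeFixtureBundle()]
#' @export
setClass("PanelSpec",
    representation(nCompounds = "integer", nCellLines = "integer",
                   nTissues = "integer", missingRate = "numeric",
                   baselineGI50Mean = "numeric", baselineGI50SD = "numeric",
                   noiseSD = "numeric", plantedEffects = "data.frame",
                   mutationRate = "numeric", nBackgroundGenes = "integer",
                   families = "integer", seed = "integer"))

setValidity("PanelSpec", function(object) {
    msgs <- character(0)
    if (object@nCompounds < 1L || object@nCellLines < 1L || object@nTissues < 1L)
        msgs <- c(msgs, "panel dimensions must be positive")
    for (p in c("missingRate", "mutationRate")) {
        v <- slot(object, p)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msgs <- c(msgs, sprintf("%s must be a probability in [0, 1]", p))
    }
    if (object@baselineGI50SD < 0 || object@noiseSD < 0)
        msgs <- c(msgs, "standard deviations must be non-negative")
    pe <- object@plantedEffects
    need <- c("compound_id", "gene", "effect_log2", "n_carriers")
    if (!all(need %in% colnames(pe)))
        msgs <- c(msgs, sprintf("plantedEffects needs columns: %s",
                                paste(need, collapse = ", ")))
    else if (nrow(pe)) {
        if (any(pe$n_carriers > object@nCellLines))
            msgs <- c(msgs, "n_carriers exceeds nCellLines")
        if (anyDuplicated(pe[, c("compound_id", "gene")]))
            msgs <- c(msgs, "duplicate planted (compound, gene) pair")
    }
    if (length(object@families) &&
        (is.null(names(object@families)) || anyDuplicated(names(object@families))))
        msgs <- c(msgs, "families must be uniquely named")
    if (length(msgs)) msgs else TRUE
})
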