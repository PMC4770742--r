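#' Construct a ResponseExperiment
#'
#' @param gi50 numeric matrix of GI50 values (minus log10 molar IC50),
#'   rows = compounds, columns = cell lines; `NA` where untested.
#' @param tested logical mask of the same shape; defaults to
#'   `!is.na(gi50)`.
#' @return a [ResponseExperiment-class].
#' @examples
#' m <- matrix(c(6, 6, 5, 7, NA, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("NSC-1", "NSC-2"), c("A", "B", "C")))
#' re <- ResponseExperiment(m)
#' gi50(re)
#' testedMask(re)
#' @rdname ResponseExperiment-class
#' @export
ResponseExperiment <- function(gi50, tested = !is.na(gi50)) {
    stopifnot(is.matrix(gi50), is.logical(tested),
              all(dim(gi50) == dim(tested)))
    g <- gi50
    g[!tested] <- NA_real_
    new("ResponseExperiment",
        SummarizedExperiment(assays = SimpleList(gi50 = g, tested = tested)))
}

.NormalizedResponse <- function(log2NormIC50, tested) {
    v <- log2NormIC50
    v[!tested] <- NA_real_
    new("NormalizedResponse",
        SummarizedExperiment(assays = SimpleList(log2NormIC50 = v,
                                                 tested = tested)))
}

#' Construct a NormalizedResponse directly
#'
#' Mainly useful for simulation studies of the response-calling rule;
#' ordinary pipelines obtain one from [normalizeResponse()].
#'
#' @param log2NormIC50 numeric matrix of normalized log2 IC50 values.
#' @param tested logical mask; defaults to `!is.na(log2NormIC50)`.
#' @return a [NormalizedResponse-class].
#' @rdname NormalizedResponse-class
#' @export
NormalizedResponse <- function(log2NormIC50, tested = !is.na(log2NormIC50)) {
    stopifnot(is.matrix(log2NormIC50), is.logical(tested),
              all(dim(log2NormIC50) == dim(tested)))
    .NormalizedResponse(log2NormIC50, tested)
}

#' Construct a MutationTable
#'
#' @param records a data.frame or [S4Vectors::DataFrame] of variant
#'   calls; missing optional columns (tissue, mutation_type, chromosome,
#'   position, dbsnp_id) are filled with `NA`.
#' @param cellLineUniverse all sequenced cell lines; defaults to the
#'   distinct cell lines in `records`.
#' @return a [MutationTable-class].
#' @rdname MutationTable-class
#' @export
MutationTable <- function(records,
                          cellLineUniverse = unique(records$cell_line)) {
    rec <- DataFrame(records)
    for (f in .MUTATION_FIELDS) {
        if (!f %in% colnames(rec))
            rec[[f]] <- if (f == "position") NA_integer_ else NA_character_
    }
    rec <- rec[, .MUTATION_FIELDS]
    rec$position <- as.integer(rec$position)
    new("MutationTable", records = rec,
        cellLineUniverse = as.character(cellLineUniverse))
}

#' Construct a MutationQuery
#'
#' @param genes,dbsnpIds queried gene symbols / rs identifiers; at least
#'   one of the two sets must be non-empty.
#' @param tissues,variantClasses optional filters; `NULL` or empty means
#'   no filtering.
#' @param combineMode `"all_of"` (default; a case line carries every
#'   queried entity) or `"any_of"`.
#' @return a [MutationQuery-class].
#' @rdname MutationQuery-class
#' @export
MutationQuery <- function(genes = character(0), dbsnpIds = character(0),
                          tissues = NULL, variantClasses = NULL,
                          combineMode = c("all_of", "any_of")) {
    combineMode <- match.arg(combineMode)
    new("MutationQuery",
        genes = as.character(genes), dbsnpIds = as.character(dbsnpIds),
        tissues = as.character(tissues %||% character(0)),
        variantClasses = as.character(variantClasses %||% character(0)),
        combineMode = combineMode)
}

#' Construct a CaseControlSplit
#'
#' @param caseLines,controlLines disjoint cell-line name sets.
#' @return a [CaseControlSplit-class].
#' @rdname CaseControlSplit-class
#' @export
CaseControlSplit <- function(caseLines, controlLines) {
    new("CaseControlSplit", caseLines = as.character(caseLines),
        controlLines = as.character(controlLines))
}

## ---- accessors ----

#' @rdname ResponseExperiment-class
#' @export
setMethod("gi50", "ResponseExperiment", function(object) assay(object, "gi50"))

#' @rdname ResponseExperiment-class
#' @export
setMethod("testedMask", "SummarizedExperiment",
          function(object) assay(object, "tested"))

#' @rdname NormalizedResponse-class
#' @export
setMethod("log2NormIC50", "NormalizedResponse",
          function(object) assay(object, "log2NormIC50"))

#' @rdname ResponseCalls-class
#' @export
setMethod("callMatrix", "ResponseCalls", function(object) assay(object, "call"))

#' @rdname ResponseExperiment-class
#' @export
setMethod("compoundIds", "SummarizedExperiment", function(object) rownames(object))

#' @rdname ResponseExperiment-class
#' @export
setMethod("cellLineIds", "SummarizedExperiment", function(object) colnames(object))

#' @rdname MutationTable-class
#' @export
setMethod("mutationRecords", "MutationTable", function(object) object@records)

#' @rdname MutationTable-class
#' @export
setMethod("cellLineUniverse", "MutationTable",
          function(object) object@cellLineUniverse)

#' @rdname CaseControlSplit-class
#' @export
setMethod("caseLines", "CaseControlSplit", function(object) object@caseLines)

#' @rdname CaseControlSplit-class
#' @export
setMethod("controlLines", "CaseControlSplit",
          function(object) object@controlLines)

## ---- show ----

setMethod("show", "MutationTable", function(object) {
    cat(sprintf("MutationTable: %d variant calls, %d genes, %d of %d cell lines with calls\n",
                nrow(object@records), length(unique(object@records$gene)),
                length(unique(object@records$cell_line)),
                length(object@cellLineUniverse)))
    invisible(NULL)
})

setMethod("show", "MutationQuery", function(object) {
    cat("MutationQuery:", object@combineMode, "of {",
        paste(c(object@genes, object@dbsnpIds), collapse = ", "), "}\n")
    if (length(object@tissues))
        cat("  tissues:", paste(object@tissues, collapse = ", "), "\n")
    if (length(object@variantClasses))
        cat("  variant classes:", paste(object@variantClasses, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "CaseControlSplit", function(object) {
    cat(sprintf("CaseControlSplit: %d cases, %d controls\n",
                length(object@caseLines), length(object@controlLines)))
    invisible(NULL)
})

setMethod("show", "PanelSpec", function(object) {
    cat(sprintf("PanelSpec: %d compounds x %d cell lines (%d tissues), %d planted effect(s), seed %d\n",
                object@nCompounds, object@nCellLines, object@nTissues,
                nrow(object@plantedEffects), object@seed))
    invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
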