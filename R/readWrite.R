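.detectSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header)) "\t" else ","
}

.readDelim <- function(path, sep = NULL) {
    if (is.null(sep)) sep <- .detectSep(path)
    utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = "character", na.strings = NULL,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "")
}

.blank <- function(x) is.na(x) | x == "" | toupper(x) == "NA"

#' Read a compound x cell-line GI50 matrix
#'
#' Expects delimited text (TSV or CSV, auto-detected from the header
#' unless `sep` is given) with one header row of cell-line names and a
#' leading compound-identifier column. Empty or `NA` cells denote
#' untested combinations and become `FALSE` in the `tested` mask.
#'
#' @param path path to the delimited file.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @return a [ResponseExperiment-class] preserving file order.
#' @seealso [writeResponseMatrix()]
#' @export
readResponseMatrix <- function(path, sep = NULL) {
    df <- .readDelim(path, sep)
    if (ncol(df) < 2L)
        .inputError("response matrix '%s' needs a compound column and >= 1 cell line", path)
    ids <- df[[1L]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
        .inputError("duplicate compound ID(s) in '%s': %s", path,
                    paste(unique(dup), collapse = ", "))
    cells <- as.matrix(df[, -1L, drop = FALSE])
    tested <- !.blank(cells)
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    badIdx <- which(tested & is.na(vals), arr.ind = TRUE)
    if (nrow(badIdx))
        .inputError("non-numeric GI50 value at compound '%s', cell line '%s'",
                    ids[badIdx[1L, 1L]], colnames(cells)[badIdx[1L, 2L]])
    dimnames(vals) <- list(ids, colnames(cells))
    dimnames(tested) <- dimnames(vals)
    ResponseExperiment(vals, tested)
}

#' Write a ResponseExperiment back to delimited text
#'
#' Untested entries are written as empty cells; reading the file back
#' with [readResponseMatrix()] reproduces values and mask exactly.
#'
#' @param object a [ResponseExperiment-class].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeResponseMatrix <- function(object, path, sep = "\t") {
    m <- gi50(object)
    txt <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
    txt[is.na(m)] <- ""
    out <- cbind(compound_id = rownames(m), as.data.frame(txt))
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.DEFAULT_MUTATION_MAP <- c(
    cell_line = "Tumor_Sample_Barcode",
    gene = "Hugo_Symbol",
    tissue = "tissue",
    variant_classification = "Variant_Classification",
    mutation_type = "Variant_Type",
    chromosome = "Chromosome",
    position = "Start_position",
    dbsnp_id = "dbSNP_RS")

#' Read a MAF-style mutation table
#'
#' One variant call per row. Column names map onto the internal fields
#' through `columnMap`; defaults follow MAF conventions
#' (`Tumor_Sample_Barcode` -> cell line, `Hugo_Symbol` -> gene, ...).
#' Only the cell-line and gene columns are mandatory. dbSNP values that
#' are blank, `novel`, or otherwise not `rs`-prefixed are recorded as
#' missing.
#'
#' @param path path to the delimited file.
#' @param columnMap named character vector, internal field -> file column;
#'   entries merge over the MAF defaults.
#' @param universeFile optional path to a one-column file listing every
#'   sequenced cell line (covering lines with zero calls); by default the
#'   universe is the set of distinct cell lines observed in the table.
#' @param sep field separator; `NULL` auto-detects.
#' @return a [MutationTable-class].
#' @export
readMutationTable <- function(path, columnMap = NULL, universeFile = NULL,
                              sep = NULL) {
    map <- .DEFAULT_MUTATION_MAP
    if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
    df <- .readDelim(path, sep)
    for (f in c("cell_line", "gene"))
        if (!map[[f]] %in% colnames(df))
            .inputError("mutation table '%s' lacks mandatory column '%s' (%s)",
                        path, map[[f]], f)
    rec <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
        lapply(map, function(col) {
            if (col %in% colnames(df)) {
                v <- df[[col]]
                v[.blank(v)] <- NA_character_
                v
            } else rep(NA_character_, nrow(df))
        }))
    rec$dbsnp_id[!is.na(rec$dbsnp_id) & !grepl("^rs", rec$dbsnp_id)] <- NA_character_
    rec$position <- suppressWarnings(as.integer(rec$position))
    universe <- if (is.null(universeFile)) unique(rec$cell_line) else {
        u <- readLines(universeFile)
        u <- trimws(u[!.blank(u)])
        u <- unique(u)
        missing <- setdiff(rec$cell_line, u)
        if (length(missing))
            .inputError("universe file omits cell line(s) with calls: %s",
                        paste(missing, collapse = ", "))
        u
    }
    MutationTable(rec, cellLineUniverse = universe)
}

#' Read a drug annotation table
#'
#' Delimited text with columns `compound_id` (mandatory, unique), `name`,
#' `family`, `mechanism` and `fda_status`; missing columns and blank
#' cells become `NA`. Compounds without a family label are excluded from
#' the family-enrichment background by default (see [enrichFamilies()]).
#'
#' @param path path to the delimited file.
#' @param sep field separator; `NULL` auto-detects.
#' @return a data.frame of drug annotations.
#' @export
readDrugAnnotations <- function(path, sep = NULL) {
    df <- .readDelim(path, sep)
    if (!"compound_id" %in% colnames(df))
        .inputError("annotation table '%s' lacks column 'compound_id'", path)
    dup <- df$compound_id[duplicated(df$compound_id)]
    if (length(dup))
        .inputError("duplicate compound ID(s) in annotations: %s",
                    paste(unique(dup), collapse = ", "))
    for (f in c("name", "family", "mechanism", "fda_status")) {
        if (!f %in% colnames(df)) df[[f]] <- NA_character_
        df[[f]][.blank(df[[f]])] <- NA_character_
    }
    df[, c("compound_id", "name", "family", "mechanism", "fda_status")]
}

.sortResults <- function(df) {
    if (all(c("p_value", "score") %in% colnames(df))) {
        id <- df[[1L]]
        df <- df[order(df$p_value, -df$score, id), , drop = FALSE]
        rownames(df) <- NULL
    }
    df
}

#' Write an association result table
#'
#' TSV output formats p-values in scientific notation with three
#' significant digits; JSON output keeps full numeric precision and
#' round-trips counts exactly. Rows are ordered by p ascending, score
#' descending, then identifier, making repeated runs byte-identical.
#'
#' @param records a result data.frame from [geneToDrug()],
#'   [enrichFamilies()] or [drugToGene()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeResults <- function(records, path, format = "tsv") {
    if (!format %in% c("tsv", "json"))
        .inputError("unknown results format '%s' (use 'tsv' or 'json')", format)
    records <- .sortResults(records)
    if (format == "json") {
        jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                             auto_unbox = FALSE, digits = NA)
    } else {
        out <- records
        for (col in grep("^(p_value|q_value|p_sens|p_res)$", colnames(out), value = TRUE))
            out[[col]] <- .formatP(out[[col]])
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE, na = "NA")
    }
    invisible(path)
}
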