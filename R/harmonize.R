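#' Normalize cell-line names for cross-source matching
#'
#' Case-folds and strips every non-alphanumeric character, so that
#' NCI60-style and CCLE-style spellings of the same line (for example
#' `MDA-MB-231` vs `MDAMB231`) collapse to one key.
#'
#' @param x character vector of cell-line names.
#' @return character vector of normalized keys.
#' @export
normalizeCellLineNames <- function(x) {
    tolower(gsub("[^[:alnum:]]", "", as.character(x)))
}

.aliasKey <- function(names, aliases) {
    key <- normalizeCellLineNames(names)
    if (length(aliases)) {
        map <- stats::setNames(normalizeCellLineNames(aliases),
                               normalizeCellLineNames(names(aliases)))
        hit <- key %in% names(map)
        key[hit] <- map[key[hit]]
    }
    key
}

#' Restrict response and mutation data to their common cell lines
#'
#' Cell-line names from both sources are reduced to a shared key
#' (case-fold, strip non-alphanumerics, then the optional user alias
#' map) and both objects are restricted to the intersection. Mutation
#' cell lines are relabelled with the response-side spelling, so
#' downstream matching is by identical names. The operation is
#' idempotent.
#'
#' @param response a [ResponseExperiment-class].
#' @param mutations a [MutationTable-class].
#' @param aliases optional named character vector mapping alternative
#'   spellings to their counterpart (`names` = from, values = to);
#'   applied after normalization.
#' @return a list with elements `response`, `mutations`, and `report`
#'   (a list of `matched` pairs, `droppedResponse`, `droppedMutation`).
#' @examples
#' re <- ResponseExperiment(matrix(6, 1, 2,
#'     dimnames = list("NSC-1", c("MDA-MB-231", "HT29"))))
#' mt <- MutationTable(data.frame(cell_line = c("MDAMB231", "PC-3"),
#'                                gene = c("TP53", "PTEN")))
#' h <- harmonizeCellLines(re, mt)
#' h$report$matched
#' @export
harmonizeCellLines <- function(response, mutations, aliases = NULL) {
    rKey <- .aliasKey(cellLineIds(response), aliases)
    uKey <- .aliasKey(cellLineUniverse(mutations), aliases)
    common <- intersect(rKey, uKey)
    if (!length(common))
        .inputError("no cell lines shared between response and mutation data")
    keepR <- rKey %in% common
    canonical <- stats::setNames(cellLineIds(response)[keepR], rKey[keepR])

    rec <- mutationRecords(mutations)
    recKey <- .aliasKey(rec$cell_line, aliases)
    keepRec <- recKey %in% common
    rec <- rec[keepRec, , drop = FALSE]
    rec$cell_line <- unname(canonical[recKey[keepRec]])

    dropMut <- setdiff(cellLineUniverse(mutations)[!uKey %in% common],
                       unname(canonical))
    matched <- data.frame(
        response_name = unname(canonical[common]),
        mutation_name = cellLineUniverse(mutations)[match(common, uKey)],
        stringsAsFactors = FALSE)

    list(response = response[, keepR],
         mutations = MutationTable(as.data.frame(rec),
                                   cellLineUniverse = unname(canonical[common])),
         report = list(matched = matched,
                       droppedResponse = cellLineIds(response)[!keepR],
                       droppedMutation = dropMut))
}
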