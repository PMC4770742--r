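#' Select case and control cell lines for a mutation query
#'
#' A cell line is a case if, after restricting its variant calls to the
#' query's tissue and variant-classification filters, it carries a
#' qualifying mutation in all (`combineMode = "all_of"`) or any
#' (`"any_of"`) of the queried genes / dbSNP ids. The tissue filter also
#' restricts the control side: controls are the filtered universe minus
#' the cases. Queried entities matching no line raise a warning and
#' contribute no lines.
#'
#' @param mutations a [MutationTable-class] (normally harmonized first).
#' @param query a [MutationQuery-class].
#' @return a [CaseControlSplit-class].
#' @export
selectCaseLines <- function(mutations, query) {
    validObject(query)
    rec <- mutationRecords(mutations)
    universe <- cellLineUniverse(mutations)
    lineTissue <- tapply(rec$tissue, rec$cell_line,
                         function(x) x[!is.na(x)][1L])
    if (length(query@tissues)) {
        tis <- lineTissue[universe]
        universe <- universe[!is.na(tis) & tis %in% query@tissues]
        rec <- rec[rec$cell_line %in% universe, , drop = FALSE]
    }
    if (length(query@variantClasses))
        rec <- rec[!is.na(rec$variant_classification) &
                   rec$variant_classification %in% query@variantClasses, ,
                   drop = FALSE]
    entitySets <- c(
        lapply(stats::setNames(nm = query@genes), function(g)
            unique(rec$cell_line[rec$gene == g])),
        lapply(stats::setNames(nm = query@dbsnpIds), function(s)
            unique(rec$cell_line[!is.na(rec$dbsnp_id) & rec$dbsnp_id == s])))
    absent <- names(entitySets)[lengths(entitySets) == 0L]
    if (length(absent))
        warning(sprintf("query entit%s matching no cell line: %s",
                        if (length(absent) > 1L) "ies" else "y",
                        paste(absent, collapse = ", ")), call. = FALSE)
    cases <- if (query@combineMode == "all_of")
        Reduce(intersect, entitySets)
    else unique(unlist(entitySets))
    cases <- intersect(universe, cases)
    if (!length(cases))
        .emptyError("no case cell line carries the queried mutation set {%s}",
                    paste(c(query@genes, query@dbsnpIds), collapse = ", "))
    CaseControlSplit(cases, setdiff(universe, cases))
}

#' Enrichment score and one-tailed Fisher test for a 2x2 response table
#'
#' The score is the fraction of good responses among cases multiplied by
#' the fraction of bad responses among controls; it lies in \\[0, 1\\] and
#' reaches 1 only at perfect separation. The p-value is the one-tailed
#' Fisher exact test for enrichment of good responses in cases: the
#' upper-tail hypergeometric probability of observing at least
#' `nCaseGood` good responses among the case draws given the table
#' margins. All arguments are vectorized.
#'
#' @param nCaseGood,nCaseBad,nCtrlGood,nCtrlBad non-negative counts;
#'   each group (cases, controls) must contain at least one observation.
#' @return a list with numeric vectors `score` and `p`.
#' @examples
#' scoreAndTest(3, 0, 0, 7)   # score 1, p = 1/choose(10, 3)
#' scoreAndTest(4, 1, 2, 8)   # score 0.64, p ~= 0.047
#' @export
scoreAndTest <- function(nCaseGood, nCaseBad, nCtrlGood, nCtrlBad) {
    counts <- cbind(nCaseGood, nCaseBad, nCtrlGood, nCtrlBad)
    if (any(counts < 0) || any(counts != round(counts)))
        .inputError("counts must be non-negative integers")
    nCase <- nCaseGood + nCaseBad
    nCtrl <- nCtrlGood + nCtrlBad
    if (any(nCase < 1L) || any(nCtrl < 1L))
        .inputError("each of the case and control groups needs >= 1 observation")
    score <- (nCaseGood / nCase) * (nCtrlBad / nCtrl)
    p <- stats::phyper(nCaseGood - 1L, nCaseGood + nCtrlGood,
                       nCaseBad + nCtrlBad, nCase, lower.tail = FALSE)
    list(score = as.numeric(score), p = pmin(as.numeric(p), 1))
}

.annotateCompounds <- function(df, annotations) {
    ann <- if (is.null(annotations))
        data.frame(compound_id = character(0), name = character(0),
                   family = character(0), mechanism = character(0),
                   fda_status = character(0), stringsAsFactors = FALSE)
    else annotations
    idx <- match(df$compound_id, ann$compound_id)
    for (f in c("name", "family", "mechanism", "fda_status"))
        df[[f]] <- if (nrow(ann)) as.character(ann[[f]])[idx] else NA_character_
    df
}

#' Rank compounds by selective activity on a mutation-defined case group
#'
#' For every compound the tested case and control cell lines are split
#' into good/bad responders; compounds with at least `minCase` tested
#' cases and `minCtrl` tested controls are scored with [scoreAndTest()]
#' and ranked by p ascending, score descending, then compound id. The
#' `significant` flag marks `p < pSig` and `score > scoreSig`. A
#' Benjamini-Hochberg `q_value` over the tested compounds is included
#' alongside the raw p-values.
#'
#' @param calls a [ResponseCalls-class] on the harmonized panel.
#' @param split a [CaseControlSplit-class] from [selectCaseLines()].
#' @param annotations optional drug-annotation data.frame
#'   (see [readDrugAnnotations()]).
#' @param minCase,minCtrl minimum tested case / control lines per scored
#'   compound (defaults 2 and 5).
#' @param pSig,scoreSig significance thresholds (defaults 0.05 and 0.3).
#' @return a data.frame of per-compound association records.
#' @export
geneToDrug <- function(calls, split, annotations = NULL,
                       minCase = 2L, minCtrl = 5L,
                       pSig = 0.05, scoreSig = 0.3) {
    m <- callMatrix(calls)
    caseCols <- intersect(caseLines(split), colnames(m))
    ctrlCols <- intersect(controlLines(split), colnames(m))
    if (!length(caseCols))
        .emptyError("no case cell line present in the response panel")
    cg <- rowSums(m[, caseCols, drop = FALSE] == "good", na.rm = TRUE)
    cb <- rowSums(m[, caseCols, drop = FALSE] == "bad", na.rm = TRUE)
    tg <- rowSums(m[, ctrlCols, drop = FALSE] == "good", na.rm = TRUE)
    tb <- rowSums(m[, ctrlCols, drop = FALSE] == "bad", na.rm = TRUE)
    keep <- (cg + cb) >= minCase & (tg + tb) >= minCtrl
    if (any(!keep))
        .log("geneToDrug: skipped %d compound(s) with < %d tested cases or < %d tested controls",
             sum(!keep), minCase, minCtrl)
    if (!any(keep))
        .emptyError("no compound passes the minimum tested-count guards")
    st <- scoreAndTest(cg[keep], cb[keep], tg[keep], tb[keep])
    df <- data.frame(compound_id = rownames(m)[keep],
                     n_case_good = unname(cg[keep]), n_case_bad = unname(cb[keep]),
                     n_ctrl_good = unname(tg[keep]), n_ctrl_bad = unname(tb[keep]),
                     score = st$score, p_value = st$p,
                     stringsAsFactors = FALSE)
    df$q_value <- stats::p.adjust(df$p_value, method = "BH")
    df$significant <- df$p_value < pSig & df$score > scoreSig
    df <- .annotateCompounds(df, annotations)
    df <- df[, c("compound_id", "name", "family", "mechanism", "fda_status",
                 "n_case_good", "n_case_bad", "n_ctrl_good", "n_ctrl_bad",
                 "score", "p_value", "q_value", "significant")]
    .sortResults(df)
}

#' Drug-family enrichment among high-scoring compounds
#'
#' Tests each drug family for over-representation among compounds whose
#' enrichment score exceeds `scoreThreshold`, with a one-tailed Fisher
#' test on the 2x2 table (in family vs not) x (passing vs not). The
#' background is the set of scored compounds with a non-null family
#' label (`background = "annotated"`, default) or every scored compound
#' (`"all"`).
#'
#' @param records a gene-to-drug result data.frame (annotated).
#' @param annotations optional annotation table used when `records`
#'   lacks family labels.
#' @param scoreThreshold minimum score defining a passing compound
#'   (default 0.6).
#' @param background `"annotated"` or `"all"`.
#' @return a data.frame of per-family enrichment records, ranked by p
#'   ascending then family label.
#' @export
enrichFamilies <- function(records, annotations = NULL, scoreThreshold = 0.6,
                           background = c("annotated", "all")) {
    background <- match.arg(background)
    df <- records
    if (!"family" %in% colnames(df) || all(is.na(df$family)))
        df <- .annotateCompounds(df[, setdiff(colnames(df),
              c("name", "family", "mechanism", "fda_status")), drop = FALSE],
              annotations)
    if (all(is.na(df$family)))
        .inputError("no compound carries a drug-family annotation")
    if (background == "annotated")
        df <- df[!is.na(df$family), , drop = FALSE]
    pass <- df$score > scoreThreshold
    if (!any(pass))
        warning("no compound exceeds the family score threshold; all family p-values are 1",
                call. = FALSE)
    fams <- sort(unique(df$family[!is.na(df$family)]))
    N <- nrow(df)
    K <- sum(pass)
    res <- do.call(rbind, lapply(fams, function(f) {
        inFam <- !is.na(df$family) & df$family == f
        nf <- sum(inFam)
        nfs <- sum(inFam & pass)
        data.frame(family = f, n_family_sig = nfs, n_family_total = nf,
                   n_background_sig = K, n_background_total = N,
                   p_value = stats::phyper(nfs - 1L, K, N - K, nf,
                                           lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    }))
    res$p_value <- pmin(res$p_value, 1)
    res <- res[order(res$p_value, res$family), , drop = FALSE]
    rownames(res) <- NULL
    res
}

.dedupKeyRecords <- function(rec) {
    key <- paste(rec$cell_line, rec$gene, rec$variant_classification,
                 rec$position, rec$dbsnp_id, sep = "\r")
    rec[!duplicated(key), , drop = FALSE]
}

.mutationKey <- function(rec) {
    vc <- ifelse(is.na(rec$variant_classification), ".",
                 rec$variant_classification)
    snp <- ifelse(is.na(rec$dbsnp_id), ".", rec$dbsnp_id)
    paste(rec$gene, vc, snp, sep = "|")
}

#' Mutations enriched in sensitive or resistant lines for one compound
#'
#' The compound's good- and bad-response cell lines define the two
#' groups. For each distinct mutation key (gene + variant classification
#' + dbSNP id when present) surviving the filters, the sensitivity
#' statistic treats the good-response lines as cases and mutation
#' carriage as the "good" outcome; the resistance statistic is the
#' mirrored test with the two groups swapped. Volcano-style flags mark
#' keys with `p < pSig` and `score > scoreSig` in one direction;
#' `bubble_size` counts the raw variant-call rows supporting the key
#' (before per-line deduplication).
#'
#' @param calls a [ResponseCalls-class] on the harmonized panel.
#' @param compoundId the queried compound.
#' @param mutations a harmonized [MutationTable-class].
#' @param tissues,variantClasses optional filters on the variant calls.
#' @param minTested minimum tested cell lines for the compound
#'   (default 10).
#' @param pSig,scoreSig flag thresholds (defaults 0.05 and 0.3).
#' @return a data.frame of volcano records, one per mutation key,
#'   ordered by best p ascending.
#' @export
drugToGene <- function(calls, compoundId, mutations,
                       tissues = NULL, variantClasses = NULL,
                       minTested = 10L, pSig = 0.05, scoreSig = 0.3) {
    m <- callMatrix(calls)
    if (!compoundId %in% rownames(m))
        .inputError("compound '%s' not present in the response panel", compoundId)
    row <- m[compoundId, ]
    if (sum(!is.na(row)) < minTested)
        .inputError("compound '%s' tested on %d cell lines (< %d required)",
                    compoundId, sum(!is.na(row)), minTested)
    good <- names(row)[!is.na(row) & row == "good"]
    bad <- names(row)[!is.na(row) & row == "bad"]
    if (!length(good) || !length(bad))
        .emptyError("compound '%s' lacks a non-empty good or bad response group",
                    compoundId)
    rec <- mutationRecords(mutations)
    rec <- rec[rec$cell_line %in% c(good, bad), , drop = FALSE]
    if (!is.null(tissues) && length(tissues))
        rec <- rec[!is.na(rec$tissue) & rec$tissue %in% tissues, , drop = FALSE]
    if (!is.null(variantClasses) && length(variantClasses))
        rec <- rec[!is.na(rec$variant_classification) &
                   rec$variant_classification %in% variantClasses, , drop = FALSE]
    if (!nrow(rec))
        .emptyError("no variant call on the response groups of '%s' after filters",
                    compoundId)
    key <- .mutationKey(rec)
    rawCount <- table(key)
    dd <- .dedupKeyRecords(rec)
    ddKey <- .mutationKey(dd)
    keys <- sort(unique(ddKey))
    res <- do.call(rbind, lapply(keys, function(k) {
        sub <- dd[ddKey == k, , drop = FALSE]
        carriers <- unique(sub$cell_line)
        gIn <- length(intersect(carriers, good))
        bIn <- length(intersect(carriers, bad))
        sens <- scoreAndTest(gIn, length(good) - gIn, bIn, length(bad) - bIn)
        resi <- scoreAndTest(bIn, length(bad) - bIn, gIn, length(good) - gIn)
        data.frame(gene = sub$gene[1L],
                   variant_classification = sub$variant_classification[1L],
                   dbsnp_id = sub$dbsnp_id[1L],
                   n_good_bearing = gIn, n_good_total = length(good),
                   n_bad_bearing = bIn, n_bad_total = length(bad),
                   score_sens = sens$score, p_sens = sens$p,
                   score_res = resi$score, p_res = resi$p,
                   bubble_size = as.integer(rawCount[[k]]),
                   stringsAsFactors = FALSE)
    }))
    sensFlag <- res$p_sens < pSig & res$score_sens > scoreSig
    resFlag <- res$p_res < pSig & res$score_res > scoreSig
    both <- sensFlag & resFlag
    sensFlag[both] <- res$p_sens[both] <= res$p_res[both]
    resFlag[both] <- !sensFlag[both]
    res$sensitivity <- sensFlag
    res$resistance <- resFlag
    ord <- order(pmin(res$p_sens, res$p_res),
                 -pmax(res$score_sens, res$score_res),
                 res$gene, res$variant_classification, res$dbsnp_id,
                 method = "radix")
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Frequency summaries of the significant volcano records
#'
#' Tallies the variant calls supporting significant (sensitivity- or
#' resistance-flagged) mutation keys by cell line, by tissue and by
#' variant classification. Each table sums to the total number of
#' contributing variant calls.
#'
#' @param volcano a [drugToGene()] result.
#' @param mutations the harmonized [MutationTable-class] used to build
#'   it.
#' @param cellLines optional restriction to a cell-line set (normally
#'   the compound's good + bad response lines, so the tallies match the
#'   volcano bubble sizes).
#' @return a list of three data.frames: `cellLines`, `tissues`,
#'   `variantClasses`, each with columns `label` and `count`.
#' @export
summarizeDistributions <- function(volcano, mutations, cellLines = NULL) {
    sig <- volcano[volcano$sensitivity | volcano$resistance, , drop = FALSE]
    empty <- data.frame(label = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
    if (!nrow(sig))
        return(list(cellLines = empty, tissues = empty, variantClasses = empty))
    rec <- mutationRecords(mutations)
    if (!is.null(cellLines))
        rec <- rec[rec$cell_line %in% cellLines, , drop = FALSE]
    sigKeys <- .mutationKey(sig)
    hit <- rec[.mutationKey(rec) %in% sigKeys, , drop = FALSE]
    tab <- function(x) {
        x <- ifelse(is.na(x), "unknown", x)
        t <- table(x)
        data.frame(label = names(t), count = as.integer(t),
                   stringsAsFactors = FALSE)
    }
    list(cellLines = tab(hit$cell_line), tissues = tab(hit$tissue),
         variantClasses = tab(hit$variant_classification))
}
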