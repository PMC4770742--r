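#' Convert GI50 to molar IC50
#'
#' GI50 is minus the log10 of the molar IC50, so the inverse transform
#' is `10^(-gi50)`. Non-finite inputs propagate as `NA` (untested).
#'
#' @param gi50 numeric vector of GI50 values (log10 units).
#' @return numeric vector of strictly positive molar concentrations.
#' @examples
#' gi50ToIC50(6)  # 1e-6 M
#' @export
gi50ToIC50 <- function(gi50) {
    out <- 10^(-gi50)
    out[!is.finite(gi50)] <- NA_real_
    out
}

#' Normalize a response matrix to per-compound relative IC50
#'
#' For each compound, GI50 is converted back to IC50 and each tested
#' entry is divided by the compound's mean IC50 across its tested cell
#' lines; the result is reported on the log2 scale. By construction the
#' linear-scale normalized IC50 of every retained compound averages to 1
#' over its tested entries. Compounds tested on fewer than `minTested`
#' cell lines are dropped with a logged reason, since the downstream
#' response-call rule is meaningless on very sparse rows.
#'
#' @param object a [ResponseExperiment-class].
#' @param minTested minimum tested entries per retained compound
#'   (default 10).
#' @return a [NormalizedResponse-class]; untested entries remain `NA`.
#' @examples
#' m <- matrix(c(6, 6, 5), 1, dimnames = list("NSC-1", c("A", "B", "C")))
#' log2NormIC50(normalizeResponse(ResponseExperiment(m), minTested = 1))
#' @export
normalizeResponse <- function(object, minTested = 10L) {
    tested <- testedMask(object)
    nTested <- rowSums(tested)
    keep <- nTested >= max(1L, minTested)
    if (any(!keep))
        .log("normalizeResponse: dropped %d compound(s) tested on < %d cell lines",
             sum(!keep), minTested)
    if (!any(keep))
        .emptyError("no compound tested on >= %d cell lines", minTested)
    ic50 <- gi50ToIC50(gi50(object))[keep, , drop = FALSE]
    tested <- tested[keep, , drop = FALSE]
    rowMean <- rowMeans(ic50, na.rm = TRUE)
    l2 <- log2(ic50 / rowMean)
    .NormalizedResponse(l2, tested)
}

#' Call good/bad responses per cell line
#'
#' For each cell line the mean and sample standard deviation of the
#' normalized log2 IC50 values of all tested compounds are computed; a
#' tested entry is called `"good"` (sensitive) when its value lies
#' strictly below `mean - k * sd`, and `"bad"` otherwise. With
#' `fixedZeroMean = TRUE` the threshold is `-k * sd` instead, anchoring
#' the cut at zero rather than at the cell line's own mean. Cell lines
#' with fewer than `minCompounds` tested compounds get no calls (all
#' untested, logged); a degenerate cell line with zero spread yields no
#' good calls, because no value can fall strictly below its mean.
#'
#' @param object a [NormalizedResponse-class].
#' @param k number of standard deviations below the centre (default 2).
#' @param minCompounds minimum tested compounds per callable cell line
#'   (default 3).
#' @param fixedZeroMean anchor the threshold at 0 instead of the column
#'   mean (default `FALSE`).
#' @return a [ResponseCalls-class] with per-line `lineMean`, `lineSD`
#'   and `nTested` in `colData`.
#' @export
callResponses <- function(object, k = 2, minCompounds = 3L,
                          fixedZeroMean = FALSE) {
    v <- log2NormIC50(object)
    n <- colSums(!is.na(v))
    mu <- colMeans(v, na.rm = TRUE)
    ss <- colSums(sweep(v, 2L, mu, "-")^2, na.rm = TRUE)
    sd <- sqrt(ss / pmax(n - 1L, 1L))
    callable <- n >= max(2L, minCompounds)
    if (any(!callable))
        .log("callResponses: %d cell line(s) with < %d tested compounds left uncalled",
             sum(!callable), minCompounds)
    centre <- if (fixedZeroMean) rep(0, length(mu)) else mu
    thr <- centre - k * sd
    thr[!callable] <- NA_real_
    call <- ifelse(sweep(v, 2L, thr, "<"), "good", "bad")
    call[, !callable] <- NA_character_
    dimnames(call) <- dimnames(v)
    mu[n == 0L] <- NA_real_
    sd[n < 2L] <- NA_real_
    new("ResponseCalls", SummarizedExperiment(
        assays = SimpleList(call = call),
        colData = DataFrame(lineMean = unname(mu), lineSD = unname(sd),
                            nTested = unname(n), row.names = colnames(v))))
}

#' Export response calls as delimited text
#'
#' Calls are encoded `G` / `B` / `.` (good / bad / untested) for audit.
#'
#' @param object a [ResponseCalls-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResponseCalls <- function(object, path) {
    m <- callMatrix(object)
    enc <- matrix(".", nrow(m), ncol(m), dimnames = dimnames(m))
    enc[!is.na(m) & m == "good"] <- "G"
    enc[!is.na(m) & m == "bad"] <- "B"
    out <- cbind(compound_id = rownames(enc), as.data.frame(enc))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
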