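## condition helpers: input/validation problems vs legitimately empty
## results get distinct classes so the CLI can map them to exit codes.

.inputError <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("pm_input_error", "pm_error")))
}

.emptyError <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("pm_empty_error", "pm_error")))
}

.log <- function(fmt, ...) message(sprintf(paste0("[pharmacomut] ", fmt), ...))

#' Format p-values for report files
#'
#' Scientific notation with 3 significant digits, fixed for byte-stable
#' output files.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @keywords internal
.formatP <- function(p) {
    out <- sprintf("%.2e", p)
    out[is.na(p)] <- "NA"
    out
}
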