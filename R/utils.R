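#' @keywords internal
"_PACKAGE"

#' @importFrom stats median var t.test var.test chisq.test wilcox.test
#'   pchisq runif rexp rlnorm setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Structured errors: every failure mode carries a condition class so callers
# (and tests) can distinguish e.g. a degenerate input from a bad argument.
p53_abort <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "p53screen_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
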