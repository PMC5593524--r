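# Fold statistics and the generic hypothesis tests used by every screen
# stage. The fold statistic is deliberately conservative: the median of the
# signal arm divided by the MAXIMUM of the control arm, so a gene only
# scores high when its weakest evidence still clears every control sample.

#' Construct a test result
#'
#' Light-weight container for a statistic / P-value pair with a label
#' recording which method produced it.
#'
#' @param statistic Numeric test statistic.
#' @param p_value Two-sided P-value in \[0, 1\].
#' @param method_label One of `"pooled-t"`, `"welch-t"`, `"f-variance"`,
#'   `"chi2-df1"`, `"mann-whitney-exact"`, `"mann-whitney-normal"`,
#'   `"log-rank"`.
#' @return An object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, method_label) {
  labels <- c("pooled-t", "welch-t", "f-variance", "chi2-df1",
              "mann-whitney-exact", "mann-whitney-normal", "log-rank")
  if (!method_label %in% labels) {
    p53_abort(sprintf("unknown method_label '%s'", method_label),
              "invalid_argument")
  }
  if (!is_prob(p_value)) {
    p53_abort("p_value must be a probability in [0, 1]", "invalid_argument")
  }
  structure(list(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 method_label = method_label),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.6g, p = %.4g\n",
              x$method_label, x$statistic, x$p_value))
  invisible(x)
}

check_intensities <- function(x, what) {
  if (length(x) == 0) {
    p53_abort(sprintf("%s values must be non-empty", what), "invalid_argument")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    p53_abort(sprintf("%s values must be finite and non-negative", what),
              "invalid_argument")
  }
}

#' Fold statistic for the cell-line screen
#'
#' `median(induced) / max(control)`: the induction fold of a probe in p53
#' wild-type, drug-treated cells relative to the strongest signal seen in
#' any control sample (untreated wild-type plus all p53-null samples).
#' Scale-invariant: multiplying both pools by the same positive constant
#' leaves the fold unchanged.
#'
#' @param induced_values Intensities in the induced arm (non-negative,
#'   linear scale).
#' @param control_values Intensities in the pooled control arm.
#' @return The fold ratio (a single number, >= 0).
#' @export
fold_induced <- function(induced_values, control_values) {
  check_intensities(induced_values, "induced")
  check_intensities(control_values, "control")
  mx <- max(control_values)
  if (mx == 0) {
    p53_abort("maximum control intensity is zero: fold undefined",
              "undefined_fold")
  }
  median(induced_values) / mx
}

#' Fold statistic for the tumor-cohort screen
#'
#' `median(wild-type tumors) / max(mutant tumors)`; the same conservative
#' median-over-maximum construction as [fold_induced()], applied to the
#' p53 wild-type versus p53 mutant contrast.
#'
#' @param wt_values Intensities in p53 wild-type tumors.
#' @param mut_values Intensities in p53 mutant tumors.
#' @return The fold ratio.
#' @export
fold_wt_vs_mut <- function(wt_values, mut_values) {
  fold_induced(wt_values, mut_values)
}

#' Two-sided F-test for equality of variances
#'
#' The statistic is reported as the larger-over-smaller variance ratio, so
#' swapping the groups gives an identical result.
#'
#' @param a,b Numeric vectors, each with at least two values and nonzero
#'   variance.
#' @return A [test_result()] with `method_label = "f-variance"`.
#' @export
f_test_variance <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    p53_abort("each group needs at least two values", "insufficient_data")
  }
  va <- var(a); vb <- var(b)
  if (va == 0 || vb == 0) {
    p53_abort("zero variance in a group: F-test undefined", "degenerate_input")
  }
  ft <- var.test(a, b)
  test_result(max(va, vb) / min(va, vb), ft$p.value, "f-variance")
}

#' Two-sided t-test with an F-test-gated variance rule
#'
#' With `variance_rule = "auto"` (the screening default) an F-test at
#' alpha = 0.05 decides between the pooled-variance Student t-test
#' (variances compatible) and the Welch t-test (variances differ).
#' Degenerate zero-variance groups are resolved without a t distribution:
#' equal means give p = 1, different means are perfectly separated and
#' give p = 0.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param variance_rule `"auto"`, `"pooled"` or `"welch"`.
#' @return A [test_result()] with `method_label` `"pooled-t"` or
#'   `"welch-t"`.
#' @export
t_test_two_sided <- function(a, b, variance_rule = c("auto", "pooled", "welch")) {
  variance_rule <- match.arg(variance_rule)
  if (length(a) < 2 || length(b) < 2) {
    p53_abort("each group needs at least two values", "insufficient_data")
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    # noiseless groups: perfectly separated or identical
    if (mean(a) == mean(b)) {
      return(test_result(0, 1, "pooled-t"))
    }
    return(test_result(sign(mean(a) - mean(b)) * Inf, 0, "pooled-t"))
  }
  pooled <- switch(variance_rule,
    pooled = TRUE,
    welch = FALSE,
    auto = if (va == 0 || vb == 0) FALSE else var.test(a, b)$p.value >= 0.05)
  tt <- t.test(a, b, var.equal = pooled)
  test_result(unname(tt$statistic), tt$p.value,
              if (pooled) "pooled-t" else "welch-t")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction), one degree of freedom —
#' the over-representation statistic used by the enrichment stage.
#'
#' @param table 2x2 matrix of non-negative counts with all row and column
#'   marginals positive.
#' @return A [test_result()] with `method_label = "chi2-df1"`.
#' @export
chi_squared_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    p53_abort("`table` must be a 2x2 matrix of non-negative counts",
              "invalid_argument")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    p53_abort("zero marginal: chi-squared undefined", "degenerate_table")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  test_result(unname(ct$statistic), ct$p.value, "chi2-df1")
}

#' Two-sided Mann-Whitney U test
#'
#' The P-value is exact (full enumeration of rank assignments) when the
#' combined sample size is at most 12 and the pooled values are tie-free;
#' otherwise a continuity-corrected normal approximation with tie
#' correction is used. The statistic is the U count for the first sample.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A [test_result()] whose `method_label` records which path was
#'   taken (`"mann-whitney-exact"` or `"mann-whitney-normal"`).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    p53_abort("both groups must be non-empty", "insufficient_data")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result(unname(wt$statistic), min(1, wt$p.value),
              if (exact) "mann-whitney-exact" else "mann-whitney-normal")
}

#' Two-group log-rank test
#'
#' Standard chi-squared (df = 1) log-rank statistic over the pooled
#' distinct event times, computed via [survival::survdiff()].
#'
#' @param times_a,times_b Strictly positive follow-up times.
#' @param events_a,events_b Event indicators (1 = event observed,
#'   0 = censored).
#' @return A [test_result()] with `method_label = "log-rank"`.
#' @export
log_rank <- function(times_a, events_a, times_b, events_b) {
  check_survival_input(times_a, events_a)
  check_survival_input(times_b, events_b)
  if (sum(events_a) + sum(events_b) == 0) {
    p53_abort("no events in either group: log-rank undefined",
              "degenerate_input")
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  test_result(sd$chisq, pchisq(sd$chisq, df = 1, lower.tail = FALSE),
              "log-rank")
}

check_survival_input <- function(times, events) {
  if (length(times) != length(events)) {
    p53_abort("times and events must have equal length", "invalid_argument")
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    p53_abort("survival times must be strictly positive", "invalid_argument")
  }
  if (!all(events %in% c(0, 1))) {
    p53_abort("event flags must be 0 or 1", "invalid_argument")
  }
}
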