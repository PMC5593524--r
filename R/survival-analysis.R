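# Median-split survival stratification: dichotomize a cohort at the
# median expression of one gene, estimate Kaplan-Meier curves per group,
# and compare them with the log-rank test. Tissue-type contrasts use the
# Mann-Whitney U test.

#' Median split of per-sample expression
#'
#' Samples strictly above the median go to `high`; samples at or below
#' the median go to `low` (ties at the median are assigned low, a
#' deterministic rule). Rank-based, hence invariant under strictly
#' monotone transforms of expression.
#'
#' @param expression Named numeric vector (names are sample ids), at
#'   least two samples.
#' @return Factor with levels `high`, `low`, named like the input.
#' @export
median_split <- function(expression) {
  if (length(expression) < 2) {
    p53_abort("median split needs at least two samples", "insufficient_data")
  }
  if (length(unique(expression)) == 1) {
    p53_abort("all expression values identical: split degenerate",
              "degenerate_split")
  }
  m <- median(expression)
  setNames(factor(ifelse(expression > m, "high", "low"),
                  levels = c("high", "low")),
           names(expression))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and extracts a compact step-function
#' summary. Samples censored at an event time are counted at risk for
#' that event (the standard convention). The median survival is the
#' smallest time at which the curve reaches 0.5 or below, `NA` if it
#' never does.
#'
#' @param times Strictly positive follow-up times (years).
#' @param events Event flags (1 = death observed, 0 = censored).
#' @return An object of class `km_estimate` with `event_times` (distinct
#'   times with at least one event), `survival_prob`, `at_risk`,
#'   `median_survival`, `n`, `n_events`.
#' @export
km_estimate <- function(times, events) {
  check_survival_input(times, events)
  if (length(times) < 1) p53_abort("no records", "insufficient_data")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  has_event <- fit$n.event > 0
  surv <- fit$surv[has_event]
  tt <- fit$time[has_event]
  med <- if (any(surv <= 0.5)) tt[which(surv <= 0.5)[1]] else NA_real_
  structure(list(event_times = tt,
                 survival_prob = surv,
                 at_risk = fit$n.risk[has_event],
                 median_survival = med,
                 n = length(times),
                 n_events = sum(events)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, events = %d, median survival = %s\n",
              x$n, x$n_events,
              if (is.na(x$median_survival)) "not reached"
              else format(x$median_survival, digits = 4)))
  invisible(x)
}

#' Plot a Kaplan-Meier estimate as a step function
#'
#' @param x A [km_estimate()].
#' @param add Add to an existing plot.
#' @param col Line colour.
#' @param ... Passed to the underlying plotting call.
#' @export
plot.km_estimate <- function(x, add = FALSE, col = "black", ...) {
  tt <- c(0, x$event_times)
  ss <- c(1, x$survival_prob)
  if (!add) {
    graphics::plot(tt, ss, type = "s", ylim = c(0, 1), col = col,
                   xlab = "Time (years)", ylab = "Survival probability", ...)
  } else {
    graphics::lines(tt, ss, type = "s", col = col, ...)
  }
  invisible(x)
}

#' Survival stratified by the expression of one gene
#'
#' Performs the median split, estimates per-group Kaplan-Meier curves,
#' and compares the groups with the log-rank test.
#'
#' @param expression Named numeric vector of one gene's expression,
#'   names are sample ids.
#' @param records Data frame with `sample_id`, `time_years` (or `time`),
#'   `event`. Sample ids must align with `expression` (every record needs
#'   an expression value).
#' @return A list of class `survival_split`: `high` and `low`
#'   [km_estimate()]s, `logrank` ([test_result()]), and `groups` (the
#'   split factor).
#' @export
survival_by_expression <- function(expression, records) {
  tcol <- if ("time_years" %in% names(records)) "time_years" else "time"
  if (!all(c("sample_id", tcol, "event") %in% names(records))) {
    p53_abort("records need sample_id, time_years (or time), event columns",
              "data_error")
  }
  missing <- setdiff(records$sample_id, names(expression))
  if (length(missing)) {
    p53_abort(sprintf("no expression value for sample(s): %s",
                      paste(missing, collapse = ", ")), "data_error")
  }
  expr <- expression[records$sample_id]
  groups <- median_split(expr)
  hi <- groups == "high"
  km_high <- km_estimate(records[[tcol]][hi], records$event[hi])
  km_low <- km_estimate(records[[tcol]][!hi], records$event[!hi])
  lr <- log_rank(records[[tcol]][hi], records$event[hi],
                 records[[tcol]][!hi], records$event[!hi])
  structure(list(high = km_high, low = km_low, logrank = lr,
                 groups = groups),
            class = "survival_split")
}

#' @export
print.survival_split <- function(x, ...) {
  fmt <- function(m) if (is.na(m)) "not reached" else format(m, digits = 4)
  cat(sprintf(paste0("<survival_split> high: n = %d, median = %s | ",
                     "low: n = %d, median = %s | log-rank p = %.4g\n"),
              x$high$n, fmt(x$high$median_survival),
              x$low$n, fmt(x$low$median_survival), x$logrank$p_value))
  invisible(x)
}

#' Pairwise tissue-type expression comparisons
#'
#' Mann-Whitney U tests between each pair of tissue types (normal,
#' tumor, metastatic). With `restrict_to_complete = TRUE` only samples
#' from patients represented in every present tissue type are used (the
#' matched-patient comparison); this mode requires `patients`.
#'
#' @param expression Named numeric vector of one gene's expression.
#' @param tissue_labels Character vector of tissue types aligned with
#'   `expression` (same names or same order).
#' @param patients Optional patient ids aligned with `expression`.
#' @param restrict_to_complete Restrict to patients with all present
#'   tissue types.
#' @return Data frame with one row per tested pair: `group1`, `group2`,
#'   `n1`, `n2`, `statistic`, `p_value`, `method`. Pairs where a group
#'   has fewer than two samples are skipped with a warning.
#' @export
compare_tissues <- function(expression, tissue_labels, patients = NULL,
                            restrict_to_complete = FALSE) {
  if (length(tissue_labels) != length(expression)) {
    p53_abort("tissue_labels must align with expression", "invalid_argument")
  }
  keep <- rep(TRUE, length(expression))
  if (restrict_to_complete) {
    if (is.null(patients)) {
      p53_abort("restrict_to_complete requires patient ids", "invalid_argument")
    }
    types <- unique(tissue_labels)
    per_patient <- split(tissue_labels, patients)
    complete <- names(per_patient)[vapply(per_patient, function(tt)
      all(types %in% tt), logical(1))]
    keep <- patients %in% complete
  }
  expression <- expression[keep]
  tissue_labels <- tissue_labels[keep]
  types <- sort(unique(tissue_labels))
  if (length(types) < 2) {
    p53_abort("need at least two tissue types", "insufficient_data")
  }
  pairs <- utils::combn(types, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- expression[tissue_labels == pr[1]]
    b <- expression[tissue_labels == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("compare_tissues: pair %s vs %s skipped (< 2 samples)",
                      pr[1], pr[2]), call. = FALSE)
      return(NULL)
    }
    res <- mann_whitney_u(a, b)
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(a), n2 = length(b),
               statistic = res$statistic, p_value = res$p_value,
               method = res$method_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), statistic = numeric(),
                      p_value = numeric(), method = character(),
                      stringsAsFactors = FALSE)
  }
  out
}
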