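# The two-stage screen: cell-line induction screen (screen 1), tumor
# cohort wild-type-vs-mutant screen (screen 2), intersection, and a
# Bonferroni gate whose denominator is the number of first-screen hits.

#' Screening configuration
#'
#' @param fold_threshold_screen1 Fold cutoff for the cell-line screen
#'   (default 3: probes must be more than 3-fold induced).
#' @param fold_threshold_screen2 Fold cutoff for the cohort screen
#'   (default 2).
#' @param alpha Per-screen P-value cutoff (default 0.05).
#' @param bonferroni_alpha Family-wise level for the Bonferroni gate
#'   (default 0.05; the per-gene threshold is `bonferroni_alpha /
#'   n_first_screen`).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(fold_threshold_screen1 = 3,
                          fold_threshold_screen2 = 2,
                          alpha = 0.05,
                          bonferroni_alpha = 0.05) {
  if (!is_number(fold_threshold_screen1) || fold_threshold_screen1 <= 1 ||
      !is_number(fold_threshold_screen2) || fold_threshold_screen2 <= 1) {
    p53_abort("fold thresholds must be ratios > 1", "invalid_config")
  }
  if (!is_prob(alpha) || alpha <= 0 || alpha >= 1 ||
      !is_prob(bonferroni_alpha) || bonferroni_alpha <= 0 || bonferroni_alpha >= 1) {
    p53_abort("alpha levels must lie in (0, 1)", "invalid_config")
  }
  structure(list(fold_threshold_screen1 = fold_threshold_screen1,
                 fold_threshold_screen2 = fold_threshold_screen2,
                 alpha = alpha,
                 bonferroni_alpha = bonferroni_alpha),
            class = "screen_config")
}

screen_hits_df <- function(gene = character(), best_probe = character(),
                           fold = numeric(), p_value = numeric(),
                           screen_id = character()) {
  structure(data.frame(gene = gene, best_probe = best_probe, fold = fold,
                       p_value = p_value, screen_id = screen_id,
                       stringsAsFactors = FALSE),
            class = c("screen_hits", "data.frame"))
}

#' @export
print.screen_hits <- function(x, ...) {
  id <- if (nrow(x)) x$screen_id[1] else "screen"
  cat(sprintf("<screen_hits> %s: %d genes\n", id, nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# Pool membership for screen 1. Induced: p53_wt + ADR_plus at the treated
# timepoints. Control: untreated p53_wt plus every p53_null sample.
screen1_pools <- function(design) {
  needed <- c("sample_id", "genotype", "treatment")
  if (!all(needed %in% names(design))) {
    p53_abort(sprintf("cell-line design needs columns: %s",
                      paste(needed, collapse = ", ")), "design_error")
  }
  arms <- unique(design[, c("genotype", "treatment")])
  wanted <- expand.grid(genotype = c("p53_wt", "p53_null"),
                        treatment = c("ADR_minus", "ADR_plus"),
                        stringsAsFactors = FALSE)
  have <- paste(arms$genotype, arms$treatment)
  missing <- setdiff(paste(wanted$genotype, wanted$treatment), have)
  if (length(missing)) {
    p53_abort(sprintf("design is missing condition arm(s): %s",
                      paste(missing, collapse = "; ")), "design_error")
  }
  induced <- design$sample_id[design$genotype == "p53_wt" &
                              design$treatment == "ADR_plus"]
  control <- design$sample_id[(design$genotype == "p53_wt" &
                               design$treatment == "ADR_minus") |
                              design$genotype == "p53_null"]
  list(induced = induced, control = control)
}

screen_one_probe_set <- function(values, induced_ids, control_ids,
                                 fold_fun = fold_induced) {
  ind <- values[, induced_ids, drop = FALSE]
  ctl <- values[, control_ids, drop = FALSE]
  res <- lapply(seq_len(nrow(values)), function(i) {
    iv <- ind[i, ]; cv <- ctl[i, ]
    if (var(c(iv, cv)) == 0) {
      return(NULL)  # constant probe, flagged by the caller
    }
    fold <- fold_fun(iv, cv)
    tt <- t_test_two_sided(iv, cv, "auto")
    list(fold = fold, p = tt$p_value)
  })
  res
}

#' Run the cell-line induction screen (screen 1)
#'
#' Per probe: fold = `median(p53_wt ADR+) / max(p53_wt ADR- and all
#' p53_null)` and P from an F-test-gated two-sided t-test between the same
#' two pools. A gene is reported when ANY of its probes exceeds the fold
#' threshold with P below `alpha`; the reported fold and P come from the
#' passing probe with the highest fold.
#'
#' @param matrix An [expr_matrix()] (probe level).
#' @param design Cell-line design data frame (see
#'   [read_sample_design()]); must contain all four genotype-by-treatment
#'   arms.
#' @param config A [screen_config()].
#' @return A `screen_hits` data frame with columns `gene`, `best_probe`,
#'   `fold`, `p_value`, `screen_id`.
#' @export
run_screen1 <- function(matrix, design, config = screen_config()) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(config, "screen_config"))
  pools <- screen1_pools(design)
  if (!all(c(pools$induced, pools$control) %in% colnames(matrix$values))) {
    p53_abort("design sample ids missing from the expression matrix",
              "design_error")
  }
  per_probe <- screen_one_probe_set(matrix$values, pools$induced, pools$control)
  collapse_probes(matrix$probes, per_probe,
                  fold_threshold = config$fold_threshold_screen1,
                  alpha = config$alpha, screen_id = "screen1")
}

#' Run the tumor-cohort screen (screen 2)
#'
#' Per gene: fold = `median(p53 wild-type tumors) / max(p53 mutant
#' tumors)` and P from the F-test-gated two-sided t-test between the two
#' status groups. Only samples typed `tumor` enter this screen; normal and
#' metastatic samples are excluded.
#'
#' @param matrix A gene-level [expr_matrix()].
#' @param design Cohort design data frame with `p53_status` and
#'   (optionally) `tissue_type` columns.
#' @param config A [screen_config()].
#' @return A `screen_hits` data frame with `screen_id = "screen2"`.
#' @export
run_screen2 <- function(matrix, design, config = screen_config()) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(config, "screen_config"))
  if (!all(c("sample_id", "p53_status") %in% names(design))) {
    p53_abort("cohort design needs sample_id and p53_status columns",
              "design_error")
  }
  if ("tissue_type" %in% names(design)) {
    design <- design[design$tissue_type == "tumor", , drop = FALSE]
  }
  wt <- design$sample_id[design$p53_status == "wild_type"]
  mut <- design$sample_id[design$p53_status == "mutant"]
  if (length(wt) < 2 || length(mut) < 2) {
    p53_abort("need at least two tumors per p53 status", "design_error")
  }
  if (!all(c(wt, mut) %in% colnames(matrix$values))) {
    p53_abort("design sample ids missing from the expression matrix",
              "design_error")
  }
  per_probe <- screen_one_probe_set(matrix$values, wt, mut,
                                    fold_fun = fold_wt_vs_mut)
  collapse_probes(matrix$probes, per_probe,
                  fold_threshold = config$fold_threshold_screen2,
                  alpha = config$alpha, screen_id = "screen2")
}

# Any-probe gene collapse: a gene is in when any probe passes both gates;
# the representative probe is the passing probe with the highest fold.
collapse_probes <- function(probes, per_probe, fold_threshold, alpha,
                            screen_id, fold_inclusive = FALSE) {
  skipped <- vapply(per_probe, is.null, logical(1))
  if (any(skipped)) {
    warning(sprintf("%d constant probe(s) skipped in %s",
                    sum(skipped), screen_id), call. = FALSE)
  }
  fold <- vapply(per_probe, function(r) if (is.null(r)) NA_real_ else r$fold,
                 numeric(1))
  p <- vapply(per_probe, function(r) if (is.null(r)) NA_real_ else r$p,
              numeric(1))
  fold_ok <- if (fold_inclusive) fold >= fold_threshold else fold > fold_threshold
  pass <- !skipped & fold_ok & p < alpha
  if (!any(pass)) {
    return(screen_hits_df())
  }
  idx <- which(pass)
  by_gene <- split(idx, probes$gene_symbol[idx])
  best <- vapply(by_gene, function(ix) ix[which.max(fold[ix])], integer(1))
  out <- screen_hits_df(gene = names(by_gene),
                        best_probe = probes$probe_id[best],
                        fold = fold[best],
                        p_value = p[best],
                        screen_id = screen_id)
  out[order(out$gene), , drop = FALSE]
}

#' Intersect the two screens' hit lists
#'
#' One record per gene reported by both screens, carrying both screens'
#' fold and P, a `known_target` flag from the supplied reference
#' annotation, and its complement `novel`.
#'
#' @param hits1,hits2 `screen_hits` from [run_screen1()] / [run_screen2()]
#'   (or replayed from a printed table via [table_to_hits()]).
#' @param known_targets Character vector of gene symbols already
#'   established as targets; defaults to the packaged reference list (see
#'   [known_p53_targets()]).
#' @return An `overlap_records` data frame, sorted by gene symbol, with
#'   columns `gene`, `fold1`, `p1`, `fold2`, `p2`, `bonferroni_pass`
#'   (NA until [bonferroni_filter()] is applied), `known_target`, `novel`.
#' @export
intersect_screens <- function(hits1, hits2, known_targets = known_p53_targets()) {
  common <- sort(intersect(hits1$gene, hits2$gene))
  i1 <- match(common, hits1$gene)
  i2 <- match(common, hits2$gene)
  structure(data.frame(gene = common,
                       fold1 = hits1$fold[i1],
                       p1 = hits1$p_value[i1],
                       fold2 = hits2$fold[i2],
                       p2 = hits2$p_value[i2],
                       bonferroni_pass = rep(NA, length(common)),
                       known_target = common %in% known_targets,
                       novel = !(common %in% known_targets),
                       stringsAsFactors = FALSE),
            class = c("overlap_records", "data.frame"))
}

#' @export
print.overlap_records <- function(x, ...) {
  cat(sprintf("<overlap_records> %d genes in both screens (%d novel",
              nrow(x), sum(x$novel)))
  if (!anyNA(x$bonferroni_pass)) {
    cat(sprintf(", %d Bonferroni-pass", sum(x$bonferroni_pass)))
  }
  cat(")\n")
  if (nrow(x)) print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Bonferroni gate on the second screen's P-values
#'
#' Flags each overlapping gene whose cohort-screen P-value survives
#' Bonferroni correction at level `bonferroni_alpha / n_first_screen`,
#' where the denominator is the number of genes that passed the FIRST
#' screen (the family of hypotheses carried into the second). No rows are
#' dropped; the `bonferroni_pass` flag is filled in.
#'
#' @param records An `overlap_records` data frame from
#'   [intersect_screens()].
#' @param n_first_screen Number of first-screen hits (>= 1).
#' @param config A [screen_config()].
#' @return The records with `bonferroni_pass` set.
#' @export
bonferroni_filter <- function(records, n_first_screen,
                              config = screen_config()) {
  if (!is_count(n_first_screen, min = 1L)) {
    p53_abort("n_first_screen must be a positive integer", "invalid_argument")
  }
  records$bonferroni_pass <- records$p2 < config$bonferroni_alpha / n_first_screen
  records
}

#' Replay printed screen statistics through the inclusion rules
#'
#' Turns a table of already-computed per-gene fold and P values (for
#' example a published candidate table) into a `screen_hits` object by
#' applying one screen's thresholds. Because published folds are rounded
#' to integers, the fold comparison here is inclusive (`>=`), unlike the
#' strict `>` used on freshly computed statistics.
#'
#' @param table Data frame with columns `gene`, `fold`, `p_value`.
#' @param screen_id `"screen1"` or `"screen2"`.
#' @param config A [screen_config()].
#' @return A `screen_hits` data frame of rows passing the rules.
#' @export
table_to_hits <- function(table, screen_id = c("screen1", "screen2"),
                          config = screen_config()) {
  screen_id <- match.arg(screen_id)
  thr <- switch(screen_id,
                screen1 = config$fold_threshold_screen1,
                screen2 = config$fold_threshold_screen2)
  keep <- table$fold >= thr & table$p_value < config$alpha
  out <- screen_hits_df(gene = table$gene[keep],
                        best_probe = rep("", sum(keep)),
                        fold = table$fold[keep],
                        p_value = table$p_value[keep],
                        screen_id = rep(screen_id, sum(keep)))
  out[order(out$gene), , drop = FALSE]
}

#' Packaged candidate table and known-target list
#'
#' `candidate_table()` returns the packaged 17-gene candidate table (per
#' gene: the printed cell-line fold/P, cohort fold/P, accession and, where
#' present, the PMID of the report establishing it as a p53 target).
#' `known_p53_targets()` returns the 7 genes of that table carrying a
#' reference PMID.
#'
#' @return A data frame (`candidate_table`) or character vector
#'   (`known_p53_targets`).
#' @export
candidate_table <- function() {
  path <- system.file("extdata", "table1.tsv", package = "p53screen",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname candidate_table
#' @export
known_p53_targets <- function() {
  path <- system.file("extdata", "known_targets.txt", package = "p53screen",
                      mustWork = TRUE)
  read_gene_list(path)
}

#' Summarise a full dual-screen run
#'
#' @param hits1,hits2 Per-screen hits.
#' @param overlap Overlap records after [bonferroni_filter()].
#' @param config The [screen_config()] used.
#' @return A list with `n1`, `n2`, `n_overlap`, `n_bonferroni` and the
#'   thresholds, suitable for JSON serialisation.
#' @export
screen_summary <- function(hits1, hits2, overlap, config = screen_config()) {
  list(n1 = nrow(hits1),
       n2 = nrow(hits2),
       n_overlap = nrow(overlap),
       n_bonferroni = if (anyNA(overlap$bonferroni_pass)) NA_integer_
                      else sum(overlap$bonferroni_pass),
       threshold = list(fold_screen1 = config$fold_threshold_screen1,
                        fold_screen2 = config$fold_threshold_screen2,
                        alpha = config$alpha,
                        bonferroni_alpha = config$bonferroni_alpha))
}
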