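test_that("cell-line generator is deterministic and honours its contract", {
  cfg <- cell_line_sim_config(n_genes = 30, n_targets = 3, seed = 7)
  d1 <- generate_cell_line_dataset(cfg)
  d2 <- generate_cell_line_dataset(cfg)
  expect_identical(d1, d2)
  # byte-identical TSV output for equal seeds
  f1 <- tempfile(); f2 <- tempfile()
  write_expression_matrix(d1$matrix, f1)
  write_expression_matrix(d2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))
  # all four condition arms, treated arms at every timepoint
  arms <- unique(d1$design[, c("genotype", "treatment")])
  expect_equal(nrow(arms), 4)
  treated <- d1$design[d1$design$treatment == "ADR_plus", ]
  expect_setequal(unique(treated$timepoint_hours), c(12, 24, 48))
  expect_true(all(d1$design$timepoint_hours[
    d1$design$treatment == "ADR_minus"] == 0))
  # truth table: planted iff fold > 1
  expect_equal(nrow(d1$truth), 30)
  expect_equal(sum(d1$truth$is_planted_target), 3)
  expect_true(all((d1$truth$planted_fold > 1) == d1$truth$is_planted_target))
})

test_that("noiseless planted folds are recovered exactly by the screen statistic", {
  cfg <- cell_line_sim_config(n_genes = 5, n_targets = 1, noise_cv = 0,
                              induction_fold_range = c(5, 5), seed = 1)
  d <- generate_cell_line_dataset(cfg)
  ind <- d$design$sample_id[d$design$genotype == "p53_wt" &
                            d$design$treatment == "ADR_plus"]
  ctl <- d$design$sample_id[!(d$design$genotype == "p53_wt" &
                              d$design$treatment == "ADR_plus")]
  expect_equal(fold_induced(d$matrix$values[1, ind],
                            d$matrix$values[1, ctl]), 5.0)
  expect_equal(fold_induced(d$matrix$values[3, ind],
                            d$matrix$values[3, ctl]), 1.0)
})

test_that("n_targets = 0 yields an all-null truth table", {
  d <- generate_cell_line_dataset(
    cell_line_sim_config(n_genes = 10, n_targets = 0, seed = 2))
  expect_false(any(d$truth$is_planted_target))
  expect_true(all(d$truth$planted_fold == 1.0))
})

test_that("generator configs reject invalid values with typed errors", {
  expect_error(cell_line_sim_config(n_genes = 5, n_targets = 6),
               class = "invalid_config")
  expect_error(cell_line_sim_config(baseline_mean = 0),
               class = "invalid_config")
  expect_error(cell_line_sim_config(noise_cv = -0.1),
               class = "invalid_config")
  expect_error(cell_line_sim_config(induction_fold_range = c(0.5, 2)),
               class = "invalid_config")
  expect_error(cohort_sim_config(n_wt = 1, n_mut = 0),
               class = "invalid_config")
  expect_error(cohort_sim_config(survival_hazard_ratio = 0),
               class = "invalid_config")
  expect_error(cohort_sim_config(censoring_rate = 1.2),
               class = "invalid_config")
})

test_that("tumor cohort plants suppression recoverable by the screen-2 statistic", {
  cfg <- cohort_sim_config(n_wt = 6, n_mut = 6, n_met = 3, n_normal = 3,
                           n_genes = 8, n_targets = 2, noise_cv = 0,
                           target_gene_suppression_fold = 3, seed = 5)
  co <- generate_tumor_cohort(cfg)
  tum <- co$design[co$design$tissue_type == "tumor", ]
  wt <- tum$sample_id[tum$p53_status == "wild_type"]
  mut <- tum$sample_id[tum$p53_status == "mutant"]
  expect_equal(fold_wt_vs_mut(co$matrix$values[1, wt],
                              co$matrix$values[1, mut]), 3.0)
  expect_equal(fold_wt_vs_mut(co$matrix$values[5, wt],
                              co$matrix$values[5, mut]), 1.0)
  # metastatic samples are further suppressed for planted targets
  met <- co$design$sample_id[co$design$tissue_type == "metastatic"]
  expect_lt(mean(co$matrix$values[1, met]), mean(co$matrix$values[1, mut]))
  # survival fields only on tumors; times positive; events 0/1
  expect_true(all(is.na(co$design$time_years[co$design$tissue_type != "tumor"])))
  expect_true(all(co$design$time_years[co$design$tissue_type == "tumor"] > 0))
  expect_true(all(co$design$event[co$design$tissue_type == "tumor"] %in% 0:1))
})

test_that("censoring_rate = 0 yields all-event cohorts; determinism holds", {
  cfg <- cohort_sim_config(n_wt = 10, n_mut = 10, censoring_rate = 0,
                           n_genes = 5, n_targets = 1, seed = 9)
  co <- generate_tumor_cohort(cfg)
  tum <- co$design[co$design$tissue_type == "tumor", ]
  expect_true(all(tum$event == 1))
  co2 <- generate_tumor_cohort(cfg)
  expect_identical(co, co2)
})

test_that("null screens are calibrated: pass rate of the P-gate is about alpha", {
  # no planted effect: the fraction of genes with t-test P < 0.05 should sit
  # within binomial error of 0.05 (pooled over simulations)
  set.seed(123)
  n_sims <- 15
  hits <- 0; total <- 0
  for (s in 1:n_sims) {
    d <- generate_cell_line_dataset(
      cell_line_sim_config(n_genes = 100, n_targets = 0, noise_cv = 0.2,
                           seed = 1000 + s))
    ind <- d$design$sample_id[d$design$genotype == "p53_wt" &
                              d$design$treatment == "ADR_plus"]
    ctl <- d$design$sample_id[!(d$design$genotype == "p53_wt" &
                                d$design$treatment == "ADR_plus")]
    p <- apply(d$matrix$values, 1, function(v)
      t_test_two_sided(v[ind], v[ctl])$p_value)
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  rate <- hits / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 4 * se + 0.01)
})

test_that("planted sequence sites have the advertised width, score and layout", {
  g <- generate_sequence_with_sites(
    500, list(list(offset = 100, spacer_length = 10, n_mismatches = 0)),
    seed = 3)
  expect_equal(nchar(g$sequence[[1]]), 500)
  expect_equal(g$sites$end - g$sites$start, 30)  # 20 informative + 10 spacer
  site <- substr(g$sequence[[1]], g$sites$start + 1, g$sites$end)
  expect_equal(score_window(site, 10), 20)
  g0 <- generate_sequence_with_sites(
    100, list(list(offset = 40, spacer_length = 0, n_mismatches = 0)),
    seed = 3)
  expect_equal(g0$sites$end - g0$sites$start, 20)
  # requested mismatches are planted exactly
  gm <- generate_sequence_with_sites(
    200, list(list(offset = 50, spacer_length = 4, n_mismatches = 3)),
    seed = 8)
  site_m <- substr(gm$sequence[[1]], gm$sites$start + 1, gm$sites$end)
  expect_equal(score_window(site_m, 4), 17)
  expect_equal(gm$sites$match_count, 17)
})

test_that("invalid site placements are rejected", {
  expect_error(generate_sequence_with_sites(
    40, list(list(offset = 30, spacer_length = 0, n_mismatches = 0))),
    class = "invalid_config")
  expect_error(generate_sequence_with_sites(
    200, list(list(offset = 10, spacer_length = 0, n_mismatches = 0),
              list(offset = 25, spacer_length = 0, n_mismatches = 0))),
    class = "invalid_config")
})

test_that("background perfect-match count follows the closed-form rate", {
  # P(a random 20-mer instance matches all 20 degenerate positions) =
  # (1/2)^16 * (1/4)^4 per window; count windows over spacers and compare
  # the observed perfect-hit total over many seeds to the Poisson band
  p_perfect <- (1 / 2)^16 * (1 / 4)^4
  len <- 2000
  n_windows <- sum(len - (20 + 0:13) + 1)
  n_seeds <- 300
  lambda <- n_seeds * n_windows * p_perfect
  observed <- 0
  for (s in 1:n_seeds) {
    g <- generate_sequence_with_sites(len, list(), seed = s)
    observed <- observed + nrow(scan_sites(g$sequence, min_match = 20))
  }
  expect_gte(observed, qpois(0.005, lambda))
  expect_lte(observed, qpois(0.995, lambda))
})

test_that("synthetic gene sets cover the universe and flag the planted term", {
  d <- generate_cell_line_dataset(
    cell_line_sim_config(n_genes = 50, n_targets = 5, seed = 4))
  gs <- generate_gene_sets(d$truth, seed = 4)
  expect_s3_class(gs, "gene_set_collection")
  expect_setequal(gs$background, d$truth$gene)
  expect_true("TERM_PLANTED" %in% names(gs$sets))
  expect_true(all(d$truth$gene[d$truth$is_planted_target] %in%
                  gs$sets$TERM_PLANTED$genes))
})
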