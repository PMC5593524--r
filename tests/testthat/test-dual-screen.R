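# helper: a small hand-built probe-level dataset with known structure
make_cells <- function(n_genes = 10, n_targets = 2, noise_cv = 0.2,
                       fold = c(5, 5), seed = 1) {
  generate_cell_line_dataset(cell_line_sim_config(
    n_genes = n_genes, n_targets = n_targets, noise_cv = noise_cv,
    induction_fold_range = fold, seed = seed))
}

test_that("screen 1 reports noiseless planted genes at their exact fold", {
  d <- make_cells(noise_cv = 0, seed = 3)
  hits <- suppressWarnings(run_screen1(d$matrix, d$design))
  expect_setequal(hits$gene, d$truth$gene[d$truth$is_planted_target])
  expect_true(all(hits$fold == 5.0))
  expect_true(all(hits$p_value == 0))
  expect_equal(unique(hits$screen_id), "screen1")
})

test_that("screen 1 applies the conjunctive fold AND P rule per probe", {
  # two genes x one probe, 2 replicates per arm: one gene with a huge fold
  # but noisy within-arm values (P large), one clean responder
  design <- data.frame(
    sample_id = paste0("s", 1:8),
    genotype = rep(c("p53_wt", "p53_wt", "p53_null", "p53_null"), each = 2),
    treatment = rep(c("ADR_plus", "ADR_minus"), 4),
    timepoint_hours = rep(c(24, 0), 4))
  ind <- design$sample_id[design$genotype == "p53_wt" &
                          design$treatment == "ADR_plus"]
  m <- matrix(10, nrow = 2, ncol = 8,
              dimnames = list(c("gA_p1", "gB_p1"), design$sample_id))
  m["gA_p1", ind] <- c(1000, 40)       # fold 10+, wildly noisy
  m["gB_p1", ind] <- c(60, 61)         # fold 6, tight
  mat <- expr_matrix(m, c("gA", "gB"))
  hits <- run_screen1(mat, design)
  expect_false("gA" %in% hits$gene)
  expect_true("gB" %in% hits$gene)
})

test_that("gene collapse keeps the highest-fold passing probe", {
  design <- data.frame(
    sample_id = paste0("s", 1:8),
    genotype = rep(c("p53_wt", "p53_wt", "p53_null", "p53_null"), each = 2),
    treatment = rep(c("ADR_plus", "ADR_minus"), 4),
    timepoint_hours = rep(c(24, 0), 4))
  ind <- design$sample_id[design$genotype == "p53_wt" &
                          design$treatment == "ADR_plus"]
  m <- matrix(10, nrow = 3, ncol = 8,
              dimnames = list(c("g_p1", "g_p2", "g_p3"), design$sample_id))
  m["g_p1", ind] <- c(40, 41)    # fold ~4, passes
  m["g_p2", ind] <- c(80, 81)    # fold ~8, passes, highest
  m["g_p3", ind] <- c(20, 21)    # fold ~2, fails the fold gate
  mat <- expr_matrix(m, c("g", "g", "g"))
  hits <- run_screen1(mat, design)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$best_probe, "g_p2")
  expect_equal(hits$fold, 8.0, tolerance = 0.05)
})

test_that("screen 1 demands the full four-arm design and known samples", {
  d <- make_cells(seed = 4)
  broken <- d$design[d$design$genotype != "p53_null", ]
  expect_error(run_screen1(d$matrix, broken), class = "design_error")
  renamed <- d$design
  renamed$sample_id[1] <- "missing_sample"
  expect_error(run_screen1(d$matrix, renamed), class = "design_error")
})

test_that("constant probes are skipped with a warning, not a crash", {
  d <- make_cells(n_genes = 4, n_targets = 0, noise_cv = 0, seed = 5)
  expect_warning(hits <- run_screen1(d$matrix, d$design), "constant")
  expect_equal(nrow(hits), 0)
})

test_that("screen 2 recovers noiseless suppression and excludes non-tumors", {
  co <- generate_tumor_cohort(cohort_sim_config(
    n_wt = 6, n_mut = 6, n_met = 3, n_normal = 3, n_genes = 10,
    n_targets = 2, noise_cv = 0, target_gene_suppression_fold = 3, seed = 2))
  hits <- suppressWarnings(run_screen2(co$matrix, co$design))
  expect_setequal(hits$gene, co$truth$gene[co$truth$is_planted_target])
  expect_true(all(hits$fold == 3.0))
  # dropping tissue_type must not change the tumor-only result here,
  # because met/normal samples would otherwise enter the status groups
  design_tumors <- co$design[co$design$tissue_type == "tumor", ]
  hits2 <- suppressWarnings(run_screen2(co$matrix, design_tumors))
  expect_equal(hits$gene, hits2$gene)
  expect_error(run_screen2(co$matrix,
                           design_tumors[design_tumors$p53_status == "mutant", ]),
               class = "design_error")
})

test_that("screen hit sets match a literal re-evaluation of the equations", {
  for (seed in 1:6) {
    d <- make_cells(n_genes = 20, n_targets = 4, noise_cv = 0.25,
                    fold = c(2.5, 6), seed = seed)
    hits <- run_screen1(d$matrix, d$design)
    ind <- d$design$sample_id[d$design$genotype == "p53_wt" &
                              d$design$treatment == "ADR_plus"]
    ctl <- d$design$sample_id[!(d$design$genotype == "p53_wt" &
                                d$design$treatment == "ADR_plus")]
    want <- oracle_screen(d$matrix$values, d$matrix$probes$gene_symbol,
                          ind, ctl, fold_threshold = 3)
    expect_equal(hits$gene, want)

    co <- generate_tumor_cohort(cohort_sim_config(
      n_wt = 8, n_mut = 8, n_met = 0, n_normal = 0, n_genes = 20,
      n_targets = 4, noise_cv = 0.25, target_gene_suppression_fold = 4,
      seed = seed))
    tum <- co$design[co$design$tissue_type == "tumor", ]
    h2 <- run_screen2(co$matrix, co$design)
    want2 <- oracle_screen(co$matrix$values, co$matrix$probes$gene_symbol,
                           tum$sample_id[tum$p53_status == "wild_type"],
                           tum$sample_id[tum$p53_status == "mutant"],
                           fold_threshold = 2)
    expect_equal(h2$gene, want2)
  }
})

test_that("raising fold thresholds never grows a hit set", {
  d <- make_cells(n_genes = 30, n_targets = 6, noise_cv = 0.3,
                  fold = c(2, 8), seed = 11)
  loose <- run_screen1(d$matrix, d$design,
                       screen_config(fold_threshold_screen1 = 2))
  default <- run_screen1(d$matrix, d$design)
  tight <- run_screen1(d$matrix, d$design,
                       screen_config(fold_threshold_screen1 = 6))
  expect_true(all(default$gene %in% loose$gene))
  expect_true(all(tight$gene %in% default$gene))
})

test_that("intersection carries both screens' statistics and novelty flags", {
  h1 <- table_to_hits(data.frame(gene = c("A", "B", "C"),
                                 fold = c(5, 4, 3), p_value = c(0.01, 0.02, 0.03)),
                      "screen1")
  h2 <- table_to_hits(data.frame(gene = c("B", "C", "D"),
                                 fold = c(3, 2, 5), p_value = c(1e-4, 1e-5, 1e-6)),
                      "screen2")
  ov <- intersect_screens(h1, h2, known_targets = "C")
  expect_equal(ov$gene, c("B", "C"))
  expect_equal(ov$fold1, c(4, 3))
  expect_equal(ov$fold2, c(3, 2))
  expect_equal(ov$known_target, c(FALSE, TRUE))
  expect_equal(ov$novel, c(TRUE, FALSE))
  # disjoint lists give an empty overlap
  expect_equal(nrow(intersect_screens(
    table_to_hits(data.frame(gene = "X", fold = 9, p_value = 0.01), "screen1"),
    h2, character(0))), 0)
})

test_that("Bonferroni gate divides alpha by the first-screen size on screen-2 P", {
  recs <- intersect_screens(
    table_to_hits(data.frame(gene = c("A", "B"), fold = c(5, 5),
                             p_value = c(0.01, 0.01)), "screen1"),
    table_to_hits(data.frame(gene = c("A", "B"), fold = c(3, 3),
                             p_value = c(1e-6, 0.01)), "screen2"),
    character(0))
  out <- bonferroni_filter(recs, 100)
  expect_equal(out$bonferroni_pass, c(TRUE, FALSE))  # threshold 5e-4
  # n = 1 reduces to the raw alpha gate
  out1 <- bonferroni_filter(recs, 1)
  expect_equal(out1$bonferroni_pass, c(TRUE, TRUE))
  expect_error(bonferroni_filter(recs, 0), class = "invalid_argument")
})

test_that("the packaged candidate table reproduces the published screen outcome", {
  th <- table1_hits()
  expect_equal(nrow(th$table), 17)
  # all 17 printed rows pass both screens' inclusion rules
  expect_equal(nrow(th$hits1), 17)
  expect_equal(nrow(th$hits2), 17)
  ov <- intersect_screens(th$hits1, th$hits2)
  expect_equal(nrow(ov), 17)
  expect_equal(sum(ov$novel), 10)
  expect_equal(sum(ov$known_target), 7)
  ov <- bonferroni_filter(ov, 209)
  expect_equal(sum(ov$bonferroni_pass), 16)
  expect_equal(ov$gene[!ov$bonferroni_pass], "SYTL2")
})

test_that("overlap and Bonferroni sets are nested subsets of the hit sets", {
  d <- make_cells(n_genes = 40, n_targets = 8, noise_cv = 0.2,
                  fold = c(4, 8), seed = 21)
  co <- generate_tumor_cohort(cohort_sim_config(
    n_wt = 20, n_mut = 20, n_genes = 40, n_targets = 8, noise_cv = 0.2,
    target_gene_suppression_fold = 4, seed = 21))
  h1 <- run_screen1(d$matrix, d$design)
  h2 <- run_screen2(co$matrix, co$design)
  ov <- bonferroni_filter(intersect_screens(h1, h2), max(1, nrow(h1)))
  expect_true(all(ov$gene %in% h1$gene))
  expect_true(all(ov$gene %in% h2$gene))
  expect_true(all(ov$gene[ov$bonferroni_pass] %in% ov$gene))
})
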