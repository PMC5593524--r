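# Synthetic-data generators emulating the study inputs: a two-genotype x
# treatment x timepoint cell-line design with planted p53-inducible
# genes, a tumor cohort with p53-status-coupled expression and
# expression-coupled survival, and genomic sequences with planted
# response elements. Intensities are linear-scale with multiplicative
# log-normal noise parameterized by its coefficient of variation, so a
# generated value's expectation equals the planted mean exactly and
# noise_cv = 0 reproduces the means bit-for-bit.

# log-normal draw with E[X] = mean and CV = cv (cv = 0 degenerates to the
# mean itself)
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep_len(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Cell-line simulation configuration
#'
#' Describes a two-genotype (p53 wild-type / p53 null) by treatment
#' (drug-treated / untreated) by timepoint design with a chosen number of
#' planted p53-inducible genes. Planted genes have expected intensity
#' `baseline_mean * fold` in wild-type treated samples only (fold drawn
#' per gene from `induction_fold_range`); every other gene/arm
#' combination sits at `baseline_mean`.
#'
#' @param n_genes Total genes.
#' @param n_targets Planted p53-responsive genes (first `n_targets` gene
#'   ids), `<= n_genes`.
#' @param n_replicates_per_condition Replicates per condition arm
#'   (default 3).
#' @param baseline_mean Baseline expected intensity (linear scale, > 0).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise (>= 0).
#' @param induction_fold_range Length-2 numeric `(low, high)`, both > 1:
#'   planted induction folds are drawn uniformly from this interval.
#' @param timepoints_hours Treated-arm timepoints (default 12, 24, 48);
#'   untreated arms carry timepoint 0.
#' @param seed Integer seed.
#' @return An object of class `cell_line_sim_config`.
#' @export
cell_line_sim_config <- function(n_genes = 200, n_targets = 10,
                                 n_replicates_per_condition = 3,
                                 baseline_mean = 100, noise_cv = 0.2,
                                 induction_fold_range = c(4, 8),
                                 timepoints_hours = c(12, 24, 48),
                                 seed = 1L) {
  if (!is_count(n_genes, 1L) || !is_count(n_targets) ||
      !is_count(n_replicates_per_condition, 1L)) {
    p53_abort("counts must be non-negative integers (n_genes, replicates >= 1)",
              "invalid_config")
  }
  if (n_targets > n_genes) {
    p53_abort("n_targets must not exceed n_genes", "invalid_config")
  }
  if (!is_number(baseline_mean) || baseline_mean <= 0) {
    p53_abort("baseline_mean must be > 0", "invalid_config")
  }
  if (!is_number(noise_cv) || noise_cv < 0) {
    p53_abort("noise_cv must be >= 0", "invalid_config")
  }
  if (length(induction_fold_range) != 2 || induction_fold_range[1] <= 1 ||
      induction_fold_range[2] < induction_fold_range[1]) {
    p53_abort("induction_fold_range must be (low, high) with low > 1",
              "invalid_config")
  }
  if (length(timepoints_hours) < 1 || any(timepoints_hours <= 0)) {
    p53_abort("timepoints_hours must be positive", "invalid_config")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_targets = as.integer(n_targets),
                 n_replicates_per_condition = as.integer(n_replicates_per_condition),
                 baseline_mean = baseline_mean, noise_cv = noise_cv,
                 induction_fold_range = induction_fold_range,
                 timepoints_hours = sort(unique(timepoints_hours)),
                 seed = as.integer(seed)),
            class = "cell_line_sim_config")
}

gene_ids <- function(n) sprintf("gene_%04d", seq_len(n))

#' Generate a synthetic cell-line dataset
#'
#' Produces an expression matrix, a sample design covering all four
#' genotype-by-treatment arms (treated arms at every timepoint), and a
#' truth table recording which genes were planted and at what fold.
#' Identical configurations (including the seed) give identical output.
#'
#' @param config A [cell_line_sim_config()].
#' @return A list: `matrix` ([expr_matrix()]), `design` (data frame),
#'   `truth` (data frame `gene`, `is_planted_target`, `planted_fold`).
#' @export
generate_cell_line_dataset <- function(config = cell_line_sim_config()) {
  stopifnot(inherits(config, "cell_line_sim_config"))
  set.seed(config$seed)
  genes <- gene_ids(config$n_genes)
  is_target <- seq_len(config$n_genes) <= config$n_targets
  fold <- ifelse(is_target,
                 runif(config$n_genes, config$induction_fold_range[1],
                       config$induction_fold_range[2]),
                 1.0)
  arms <- rbind(
    data.frame(genotype = "p53_wt", treatment = "ADR_minus",
               timepoint_hours = 0),
    data.frame(genotype = "p53_wt", treatment = "ADR_plus",
               timepoint_hours = config$timepoints_hours),
    data.frame(genotype = "p53_null", treatment = "ADR_minus",
               timepoint_hours = 0),
    data.frame(genotype = "p53_null", treatment = "ADR_plus",
               timepoint_hours = config$timepoints_hours))
  reps <- config$n_replicates_per_condition
  design <- arms[rep(seq_len(nrow(arms)), each = reps), , drop = FALSE]
  design$replicate <- rep(seq_len(reps), times = nrow(arms))
  design$sample_id <- sprintf("%s_%s_t%02d_r%d",
                              sub("p53_", "", design$genotype),
                              sub("ADR_", "ADR", design$treatment),
                              design$timepoint_hours, design$replicate)
  design <- design[, c("sample_id", "genotype", "treatment",
                       "timepoint_hours", "replicate")]
  rownames(design) <- NULL
  induced_arm <- design$genotype == "p53_wt" & design$treatment == "ADR_plus"
  mean_mat <- matrix(config$baseline_mean, nrow = config$n_genes,
                     ncol = nrow(design))
  mean_mat[is_target, induced_arm] <-
    config$baseline_mean * fold[is_target]
  values <- matrix(rlnorm_cv(length(mean_mat), as.vector(mean_mat),
                             config$noise_cv),
                   nrow = config$n_genes)
  rownames(values) <- paste0(genes, "_p1")
  colnames(values) <- design$sample_id
  truth <- data.frame(gene = genes, is_planted_target = is_target,
                      planted_fold = fold, stringsAsFactors = FALSE)
  list(matrix = expr_matrix(values, genes), design = design, truth = truth)
}

#' Tumor-cohort simulation configuration
#'
#' Describes a cohort of p53 wild-type and p53 mutant tumors, optional
#' metastatic and normal samples, planted target suppression in mutant
#' (and further in metastatic) samples, and survival times coupled to the
#' expression of a designated marker gene through an exponential hazard
#' model on the median split.
#'
#' @param n_wt,n_mut Number of p53 wild-type / mutant tumors
#'   (`n_wt + n_mut >= 2`).
#' @param n_met,n_normal Number of metastatic / normal samples.
#' @param n_genes,n_targets Gene universe and number of planted targets.
#' @param baseline_mean Baseline expected intensity (> 0).
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param target_gene_suppression_fold Ratio > 1 dividing planted-target
#'   expression in mutant tumors.
#' @param met_suppression_fold Additional ratio >= 1 dividing
#'   planted-target expression in metastatic samples.
#' @param survival_hazard_ratio Hazard in the low-expression group over
#'   the high-expression group of the marker gene (> 0; 1 means no
#'   survival signal).
#' @param censoring_rate Fraction of tumors censored, in \[0, 1\].
#' @param median_survival_years Baseline (high-group) median survival.
#' @param marker_gene Gene driving survival; default the first planted
#'   target (or the first gene when nothing is planted).
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_wt = 40, n_mut = 40, n_met = 10,
                              n_normal = 10, n_genes = 200, n_targets = 10,
                              baseline_mean = 100, noise_cv = 0.2,
                              target_gene_suppression_fold = 4,
                              met_suppression_fold = 2,
                              survival_hazard_ratio = 2,
                              censoring_rate = 0.3,
                              median_survival_years = 5,
                              marker_gene = NULL, seed = 1L) {
  counts_ok <- is_count(n_wt) && is_count(n_mut) && is_count(n_met) &&
    is_count(n_normal) && is_count(n_genes, 1L) && is_count(n_targets)
  if (!counts_ok) p53_abort("counts must be non-negative integers",
                            "invalid_config")
  if (n_wt + n_mut < 2) {
    p53_abort("need at least two tumors in total", "invalid_config")
  }
  if (n_targets > n_genes) {
    p53_abort("n_targets must not exceed n_genes", "invalid_config")
  }
  if (!is_number(baseline_mean) || baseline_mean <= 0 ||
      !is_number(noise_cv) || noise_cv < 0) {
    p53_abort("baseline_mean must be > 0 and noise_cv >= 0", "invalid_config")
  }
  if (!is_number(target_gene_suppression_fold) ||
      target_gene_suppression_fold <= 1 ||
      !is_number(met_suppression_fold) || met_suppression_fold < 1) {
    p53_abort("suppression folds must be > 1 (metastatic >= 1)",
              "invalid_config")
  }
  if (!is_number(survival_hazard_ratio) || survival_hazard_ratio <= 0) {
    p53_abort("survival_hazard_ratio must be > 0", "invalid_config")
  }
  if (!is_prob(censoring_rate)) {
    p53_abort("censoring_rate must lie in [0, 1]", "invalid_config")
  }
  if (!is_number(median_survival_years) || median_survival_years <= 0) {
    p53_abort("median_survival_years must be > 0", "invalid_config")
  }
  structure(list(n_wt = as.integer(n_wt), n_mut = as.integer(n_mut),
                 n_met = as.integer(n_met), n_normal = as.integer(n_normal),
                 n_genes = as.integer(n_genes),
                 n_targets = as.integer(n_targets),
                 baseline_mean = baseline_mean, noise_cv = noise_cv,
                 target_gene_suppression_fold = target_gene_suppression_fold,
                 met_suppression_fold = met_suppression_fold,
                 survival_hazard_ratio = survival_hazard_ratio,
                 censoring_rate = censoring_rate,
                 median_survival_years = median_survival_years,
                 marker_gene = marker_gene, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Generate a synthetic tumor cohort
#'
#' Gene-level expression for wild-type tumors, mutant tumors, metastatic
#' and normal samples; planted targets are divided by
#' `target_gene_suppression_fold` in mutant tumors and additionally by
#' `met_suppression_fold` in metastatic samples. Tumor samples carry
#' survival times from an exponential model: tumors at or below the
#' median expression of the marker gene have
#' `survival_hazard_ratio`-times the hazard of tumors above it.
#' Censoring is applied independently at `censoring_rate` (censored
#' follow-up is uniform over the unobserved event time).
#'
#' @param config A [cohort_sim_config()].
#' @return A list: `matrix` (gene-level [expr_matrix()]), `design` (data
#'   frame with `sample_id`, `patient_id`, `p53_status`, `tissue_type`,
#'   `time_years`, `event`; survival fields are `NA` outside tumors),
#'   `truth`, and `marker_gene`.
#' @export
generate_tumor_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  genes <- gene_ids(config$n_genes)
  is_target <- seq_len(config$n_genes) <= config$n_targets
  n_tumor <- config$n_wt + config$n_mut
  status <- c(rep("wild_type", config$n_wt), rep("mutant", config$n_mut))
  # metastatic/normal samples attach to existing patients where possible,
  # enabling the matched-patient tissue comparison
  patient_of <- function(k) {
    if (n_tumor == 0) sprintf("patient_%03d", seq_len(k) + n_tumor)
    else sprintf("patient_%03d", ((seq_len(k) - 1L) %% n_tumor) + 1L)
  }
  design <- rbind(
    data.frame(sample_id = sprintf("tumor_%03d", seq_len(n_tumor)),
               patient_id = sprintf("patient_%03d", seq_len(n_tumor)),
               p53_status = status, tissue_type = "tumor",
               stringsAsFactors = FALSE),
    if (config$n_met > 0)
      data.frame(sample_id = sprintf("met_%03d", seq_len(config$n_met)),
                 patient_id = patient_of(config$n_met),
                 p53_status = "mutant", tissue_type = "metastatic",
                 stringsAsFactors = FALSE),
    if (config$n_normal > 0)
      data.frame(sample_id = sprintf("normal_%03d", seq_len(config$n_normal)),
                 patient_id = patient_of(config$n_normal),
                 p53_status = "wild_type", tissue_type = "normal",
                 stringsAsFactors = FALSE))
  suppression <- rep(1, nrow(design))
  suppression[design$tissue_type == "tumor" &
              design$p53_status == "mutant"] <-
    config$target_gene_suppression_fold
  suppression[design$tissue_type == "metastatic"] <-
    config$target_gene_suppression_fold * config$met_suppression_fold
  mean_mat <- matrix(config$baseline_mean, nrow = config$n_genes,
                     ncol = nrow(design))
  if (any(is_target)) {
    mean_mat[is_target, ] <- config$baseline_mean /
      matrix(suppression, nrow = sum(is_target), ncol = nrow(design),
             byrow = TRUE)
  }
  values <- matrix(rlnorm_cv(length(mean_mat), as.vector(mean_mat),
                             config$noise_cv),
                   nrow = config$n_genes)
  rownames(values) <- genes
  colnames(values) <- design$sample_id
  marker <- config$marker_gene %||%
    (if (config$n_targets >= 1) genes[1] else genes[1])
  if (!marker %in% genes) {
    p53_abort(sprintf("marker gene '%s' not in the simulated universe",
                      marker), "invalid_config")
  }
  # survival for tumor samples: exponential hazards on the marker median split
  design$time_years <- NA_real_
  design$event <- NA_integer_
  tumor_idx <- which(design$tissue_type == "tumor")
  marker_expr <- values[marker, tumor_idx]
  hi <- marker_expr > median(marker_expr)
  base_hazard <- log(2) / config$median_survival_years
  hazard <- ifelse(hi, base_hazard, base_hazard * config$survival_hazard_ratio)
  t_event <- rexp(length(tumor_idx), rate = hazard)
  censored <- runif(length(tumor_idx)) < config$censoring_rate
  t_obs <- ifelse(censored, runif(length(tumor_idx)) * t_event, t_event)
  t_obs <- pmax(t_obs, .Machine$double.eps)
  design$time_years[tumor_idx] <- t_obs
  design$event[tumor_idx] <- as.integer(!censored)
  truth <- data.frame(gene = genes, is_planted_target = is_target,
                      planted_fold = ifelse(is_target,
                                            config$target_gene_suppression_fold,
                                            1.0),
                      stringsAsFactors = FALSE)
  list(matrix = expr_matrix(values, genes), design = design, truth = truth,
       marker_gene = marker)
}

#' Generate a random sequence with planted response elements
#'
#' Background is i.i.d. uniform A/C/G/T. Each planted site is a concrete
#' instance of the degenerate consensus (uniform choice at each
#' degenerate position, random spacer bases) with exactly `n_mismatches`
#' informative positions corrupted to a non-matching base. Planted sites
#' must fit inside the sequence and must not overlap.
#'
#' @param length Sequence length in bases.
#' @param sites List of site descriptors, each a list/vector with
#'   `offset` (0-based start), `spacer_length`, `n_mismatches`.
#' @param seed Integer seed.
#' @param model A [p53_motif()].
#' @return A list: `sequence` (named character scalar, name `synth_seq`),
#'   `sites` (BED6-style data frame of truth intervals: `sequence_id`,
#'   `start`, `end`, `strand`, `spacer_length`, `match_count`).
#' @export
generate_sequence_with_sites <- function(length, sites = list(), seed = 1L,
                                         model = p53_motif()) {
  if (!is_count(length, 1L)) {
    p53_abort("length must be a positive integer", "invalid_config")
  }
  set.seed(as.integer(seed))
  parse_site <- function(s) {
    s <- as.list(s)
    list(offset = as.integer(s$offset),
         spacer_length = as.integer(s$spacer_length),
         n_mismatches = as.integer(s$n_mismatches %||% 0L))
  }
  sites <- lapply(sites, parse_site)
  for (s in sites) {
    if (s$spacer_length < model$spacer_range[1] ||
        s$spacer_length > model$spacer_range[2]) {
      p53_abort("site spacer outside the model's spacer range",
                "invalid_config")
    }
    if (s$offset < 0 || s$offset + 20L + s$spacer_length > length) {
      p53_abort("planted site does not fit inside the sequence",
                "invalid_config")
    }
    if (s$n_mismatches < 0 || s$n_mismatches > 20) {
      p53_abort("n_mismatches must lie in [0, 20]", "invalid_config")
    }
  }
  if (length(sites) > 1) {
    starts <- vapply(sites, `[[`, integer(1), "offset")
    ends <- starts + 20L +
      vapply(sites, `[[`, integer(1), "spacer_length")
    ord <- order(starts)
    if (any(starts[ord][-1] < ends[ord][-length(ends)])) {
      p53_abort("planted sites overlap", "invalid_config")
    }
  }
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, length, replace = TRUE)
  syms <- pattern_symbols(model)
  truth <- lapply(sites, function(s) {
    width <- 20L + s$spacer_length
    site_chars <- sample(bases, width, replace = TRUE)  # spacer background
    info <- informative_positions(s$spacer_length)
    for (i in seq_along(syms)) {
      allowed <- IUPAC_MATCH[[syms[i]]]
      site_chars[info[i]] <- if (length(allowed) == 1) allowed
                             else sample(allowed, 1)
    }
    if (s$n_mismatches > 0) {
      corrupt <- sample(seq_along(syms), s$n_mismatches)
      for (i in corrupt) {
        disallowed <- setdiff(bases, IUPAC_MATCH[[syms[i]]])
        site_chars[info[i]] <- if (length(disallowed) == 1) disallowed
                               else sample(disallowed, 1)
      }
    }
    chars[(s$offset + 1L):(s$offset + width)] <<- site_chars
    data.frame(sequence_id = "synth_seq", start = s$offset,
               end = s$offset + width, strand = "+",
               spacer_length = s$spacer_length,
               match_count = 20L - s$n_mismatches,
               stringsAsFactors = FALSE)
  })
  truth <- if (length(truth)) do.call(rbind, truth)
           else empty_hits()[, c("sequence_id", "start", "end", "strand",
                                 "spacer_length", "match_count")]
  list(sequence = c(synth_seq = paste(chars, collapse = "")), sites = truth)
}

#' Generate a synthetic gene-set collection
#'
#' Builds a GMT-style collection over a simulated gene universe: one term
#' collecting the planted targets (padded with a few null genes) plus
#' random terms, so the over-representation stage has signal to find.
#'
#' @param truth Truth table from a generator.
#' @param n_random_sets Number of random terms (default 10).
#' @param set_size Genes per random term (default 15).
#' @param seed Integer seed.
#' @return A [gene_set_collection()] whose background is the whole
#'   simulated universe.
#' @export
generate_gene_sets <- function(truth, n_random_sets = 10, set_size = 15,
                               seed = 1L) {
  set.seed(as.integer(seed))
  genes <- truth$gene
  targets <- truth$gene[truth$is_planted_target]
  nulls <- setdiff(genes, targets)
  sets <- list()
  if (length(targets)) {
    pad <- sample(nulls, min(length(nulls), max(2, length(targets) %/% 3)))
    sets[["TERM_PLANTED"]] <- list(
      term_name = "planted target process", genes = c(targets, pad))
  }
  for (i in seq_len(n_random_sets)) {
    sets[[sprintf("TERM_%03d", i)]] <- list(
      term_name = sprintf("random process %d", i),
      genes = sample(genes, min(set_size, length(genes))))
  }
  gene_set_collection(sets, background = genes)
}
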