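# End-to-end orchestration: simulate -> screen -> enrich -> scan ->
# survive, with a validated config, per-stage logging and a consolidated
# machine-readable report. The run is deterministic for a fixed config
# and seed: the report hash covers everything except wall-clock fields.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,          # NULL -> timestamped directory under "runs"
    log_level = "info",      # "quiet" | "info"
    cells = list(n_genes = 120L, n_targets = 8L,
                 n_replicates_per_condition = 3L, baseline_mean = 100,
                 noise_cv = 0.2, induction_fold_range = c(4, 8),
                 timepoints_hours = c(12, 24, 48)),
    cohort = list(n_wt = 40L, n_mut = 40L, n_met = 10L, n_normal = 10L,
                  n_genes = 120L, n_targets = 8L, baseline_mean = 100,
                  noise_cv = 0.2, target_gene_suppression_fold = 4,
                  met_suppression_fold = 2, survival_hazard_ratio = 2,
                  censoring_rate = 0.3, median_survival_years = 5,
                  marker_gene = NULL),
    screen = list(fold_threshold_screen1 = 3, fold_threshold_screen2 = 2,
                  alpha = 0.05, bonferroni_alpha = 0.05),
    enrichment = list(p_cutoff = 0.05, score_cutoff_percent = 5,
                      n_random_sets = 10L, set_size = 15L),
    motif = list(min_match = 15L, spacer_min = 0L, spacer_max = 13L,
                 sequence_length = 3000L,
                 planted_sites = list(
                   list(offset = 500L, spacer_length = 10L, n_mismatches = 0L),
                   list(offset = 1500L, spacer_length = 0L, n_mismatches = 3L))),
    known_targets_file = NULL  # NULL -> packaged reference list
  )
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    p53_abort(sprintf("unknown config key: %s",
                      paste(c(path, unknown[1]), collapse = ".")),
              "validation_error")
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]) && !identical(key, "planted_sites")) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills every omitted key with its
#' default, rejects unknown keys (reporting the key path), and resolves
#' relative file paths against the config file's directory.
#'
#' @param config YAML path or named list (possibly partial). A minimal
#'   config is `list(seed = 7)`.
#' @return A fully-resolved config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1) {
    base_dir <- dirname(normalizePath(config, mustWork = TRUE))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    p53_abort("config must be a list or a YAML file path", "validation_error")
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is_count(cfg$seed)) {
    p53_abort("config key seed: must be an integer", "validation_error")
  }
  for (key in c("known_targets_file", "out_dir")) {
    p <- cfg[[key]]
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) {
      cfg[[key]] <- file.path(base_dir, p)
    }
  }
  if (!is.null(cfg$known_targets_file) && !file.exists(cfg$known_targets_file)) {
    p53_abort(sprintf("config key known_targets_file: '%s' does not exist",
                      cfg$known_targets_file), "validation_error")
  }
  # constructor-level validation, so bad values fail here not mid-run
  do.call(cell_line_sim_config, c(cfg$cells, list(seed = cfg$seed)))
  do.call(cohort_sim_config, c(cfg$cohort, list(seed = cfg$seed)))
  do.call(screen_config, cfg$screen)
  p53_motif(cfg$motif$spacer_min, cfg$motif$spacer_max)
  structure(cfg, class = "pipeline_config")
}

# hash over the scientific configuration only: where the run lands and
# how chatty it is do not change the result
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  cfg$log_level <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full screening pipeline
#'
#' Executes simulate, screen, enrich, scan and survive in order, writing
#' each stage's artifacts into a run directory together with a
#' machine-readable `report.json` and a plain-text log. A failure in any
#' stage aborts with a stage-tagged error.
#'
#' @param config A [validate_config()]-accepted config (list, YAML path,
#'   or `pipeline_config`).
#' @return The run report (list of class `run_report`), invisibly
#'   including `run_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  run_dir <- config$out_dir %||%
    file.path("runs", format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  if (dir.exists(run_dir) && length(list.files(run_dir))) {
    p53_abort(sprintf("run directory '%s' already exists and is non-empty",
                      run_dir), "validation_error")
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, sep = "", append = TRUE)
    if (identical(config$log_level, "info")) message(msg)
  }
  stage <- function(name, expr) {
    log_line("[%s] start", name)
    out <- tryCatch(expr, error = function(e) {
      log_line("[%s] FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_line("[%s] done", name)
    out
  }
  log_line("p53screen %s, seed %d", as.character(packageVersion("p53screen")),
           config$seed)

  sim <- stage("simulate", {
    cells <- generate_cell_line_dataset(
      do.call(cell_line_sim_config, c(config$cells, list(seed = config$seed))))
    cohort <- generate_tumor_cohort(
      do.call(cohort_sim_config, c(config$cohort, list(seed = config$seed + 1L))))
    seqgen <- generate_sequence_with_sites(
      config$motif$sequence_length, config$motif$planted_sites,
      seed = config$seed + 2L,
      model = p53_motif(config$motif$spacer_min, config$motif$spacer_max))
    write_expression_matrix(cells$matrix,
                            file.path(run_dir, "cells_matrix.tsv"))
    write_sample_design(cells$design, file.path(run_dir, "cells_design.tsv"))
    write_expression_matrix(cohort$matrix,
                            file.path(run_dir, "cohort_matrix.tsv"))
    write_sample_design(cohort$design, file.path(run_dir, "cohort_design.tsv"))
    fa <- Biostrings::DNAStringSet(seqgen$sequence)
    Biostrings::writeXStringSet(fa, file.path(run_dir, "sequence.fa"))
    write_bed6(seqgen$sites, file.path(run_dir, "planted_sites.bed"))
    list(cells = cells, cohort = cohort, seqgen = seqgen)
  })

  scfg <- do.call(screen_config, config$screen)
  screens <- stage("screen", {
    hits1 <- run_screen1(sim$cells$matrix, sim$cells$design, scfg)
    hits2 <- run_screen2(sim$cohort$matrix, sim$cohort$design, scfg)
    known <- if (is.null(config$known_targets_file)) known_p53_targets()
             else read_gene_list(config$known_targets_file)
    overlap <- intersect_screens(hits1, hits2, known)
    overlap <- bonferroni_filter(overlap, max(1L, nrow(hits1)), scfg)
    write.table(hits1, file.path(run_dir, "screen1_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(hits2, file.path(run_dir, "screen2_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(overlap, file.path(run_dir, "overlap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summ <- screen_summary(hits1, hits2, overlap, scfg)
    jsonlite::write_json(summ, file.path(run_dir, "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(hits1 = hits1, hits2 = hits2, overlap = overlap, summary = summ)
  })

  enriched <- stage("enrich", {
    collection <- generate_gene_sets(sim$cells$truth,
                                     n_random_sets = config$enrichment$n_random_sets,
                                     set_size = config$enrichment$set_size,
                                     seed = config$seed + 3L)
    res <- suppressMessages(
      enrich(screens$overlap$gene, collection,
             p_cutoff = config$enrichment$p_cutoff,
             score_cutoff_percent = config$enrichment$score_cutoff_percent))
    write.table(res, file.path(run_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res
  })

  hits <- stage("scan", {
    model <- p53_motif(config$motif$spacer_min, config$motif$spacer_max)
    h <- scan_sites(sim$seqgen$sequence, model,
                    min_match = config$motif$min_match)
    write_bed6(h, file.path(run_dir, "motif_hits.bed"))
    h
  })

  surv <- stage("survive", {
    design <- sim$cohort$design
    tumors <- design[design$tissue_type == "tumor", , drop = FALSE]
    marker <- sim$cohort$marker_gene
    expr <- sim$cohort$matrix$values[marker, tumors$sample_id]
    ss <- survival_by_expression(expr, tumors)
    out <- list(marker_gene = marker,
                median_high = ss$high$median_survival,
                median_low = ss$low$median_survival,
                logrank_p = ss$logrank$p_value)
    jsonlite::write_json(out, file.path(run_dir, "survival.json"),
                         auto_unbox = TRUE, digits = NA)
    ss
  })

  report <- list(
    package_version = as.character(packageVersion("p53screen")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = list(
      simulate = list(
        n_cell_samples = nrow(sim$cells$design),
        n_cohort_samples = nrow(sim$cohort$design),
        n_planted_cell_targets = sum(sim$cells$truth$is_planted_target),
        sequence_length = nchar(sim$seqgen$sequence[[1]]),
        n_planted_sites = nrow(sim$seqgen$sites)),
      screen = screens$summary,
      enrich = list(n_terms_reported = nrow(enriched),
                    top_term = if (nrow(enriched)) enriched$term_id[1] else NA),
      scan = list(n_motif_hits = nrow(hits),
                  best_match_count = if (nrow(hits)) max(hits$match_count)
                                     else NA),
      survive = list(marker_gene = sim$cohort$marker_gene,
                     median_high = surv$high$median_survival,
                     median_low = surv$low$median_survival,
                     logrank_p = surv$logrank$p_value)))
  report_path <- file.path(run_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  report$report_hash <- unname(tools::md5sum(report_path))
  report$run_dir <- run_dir
  log_line("pipeline complete: %s", run_dir)
  invisible(structure(report, class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$stages
  cat(sprintf(paste0("<run_report> seed %d (%s)\n",
                     "  screen: n1 = %d, n2 = %d, overlap = %d,",
                     " bonferroni = %s\n",
                     "  enrich: %d term(s); scan: %d hit(s);",
                     " log-rank p = %.4g\n"),
              x$seed, x$run_dir %||% "", s$screen$n1, s$screen$n2,
              s$screen$n_overlap, format(s$screen$n_bonferroni),
              s$enrich$n_terms_reported, s$scan$n_motif_hits,
              s$survive$logrank_p))
  invisible(x)
}
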