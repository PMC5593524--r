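# File formats: expression matrices and sample designs travel as TSV,
# gene lists as one symbol per line, motif hits and planted-site truth as
# BED6, sequences as FASTA (via Biostrings).

#' Construct an expression matrix object
#'
#' Couples a probe (or gene) by sample matrix of linear-scale, non-negative
#' intensities with a probe-to-gene map. For gene-level data (e.g. a tumor
#' cohort) probe ids and gene symbols coincide.
#'
#' @param values Numeric matrix, probes in rows (rownames are probe ids),
#'   samples in columns (colnames are sample ids). Values must be
#'   non-negative and on a linear scale; the fold statistics divide raw
#'   medians and maxima.
#' @param gene_symbols Character vector mapping each row to a gene symbol;
#'   defaults to the rownames (gene-level matrix).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `probes` (data frame with `probe_id`, `gene_symbol`).
#' @export
expr_matrix <- function(values, gene_symbols = rownames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    p53_abort("`values` must be a numeric matrix", "invalid_argument")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    p53_abort("`values` must have probe rownames and sample colnames",
              "invalid_argument")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    p53_abort("intensities must be finite and non-negative", "invalid_argument")
  }
  if (length(gene_symbols) != nrow(values)) {
    p53_abort("`gene_symbols` must have one entry per row", "invalid_argument")
  }
  structure(
    list(values = values,
         probes = data.frame(probe_id = rownames(values),
                             gene_symbol = as.character(gene_symbols))),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes (%d genes) x %d samples\n",
              nrow(x$values), length(unique(x$probes$gene_symbol)),
              ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read / write an expression matrix TSV
#'
#' The TSV layout is: first column `probe_id`, second column `gene_symbol`,
#' remaining columns one per sample.
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns an [expr_matrix()] object.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("probe_id", "gene_symbol"))) {
    p53_abort(sprintf(
      "expression TSV '%s' must start with columns probe_id, gene_symbol",
      path), "parse_error")
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$probe_id
  expr_matrix(m, df$gene_symbol)
}

#' @param x An [expr_matrix()] object.
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- cbind(x$probes, as.data.frame(x$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample design TSV
#'
#' A sample design is a data frame keyed by `sample_id`. Cell-line designs
#' carry `genotype` (`p53_wt` / `p53_null`), `treatment` (`ADR_plus` /
#' `ADR_minus`) and `timepoint_hours` (0 for untreated); cohort designs
#' carry `p53_status` (`wild_type` / `mutant`), `tissue_type`
#' (`tumor` / `normal` / `metastatic`), `time_years` and `event`.
#'
#' @param path File path.
#' @export
read_sample_design <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    p53_abort(sprintf("design TSV '%s' lacks a sample_id column", path),
              "parse_error")
  }
  df
}

#' @param design Design data frame.
#' @rdname read_sample_design
#' @export
write_sample_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#' @param path File path; blank lines and `#` comments are skipped.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write motif hits or planted-site truth as BED6
#'
#' Coordinates are 0-based half-open. The name field records the match
#' count as `n/20`; the BED score is the match count scaled by 50 onto
#' 0-1000.
#'
#' @param hits Data frame with columns `sequence_id`, `start`, `end`,
#'   `strand`, `match_count` (as returned by [scan_sites()]).
#' @param path Output path.
#' @export
write_bed6 <- function(hits, path) {
  bed <- data.frame(chrom = hits$sequence_id,
                    start = hits$start,
                    end = hits$end,
                    name = sprintf("%d/20", hits$match_count),
                    score = hits$match_count * 50L,
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
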