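# Gene-set over-representation of a candidate list against a background,
# scored by the uncorrected 2x2 Pearson chi-squared and the percentage of
# list genes annotated to the term.

#' Build a gene-set collection
#'
#' @param sets Named list: `term_id -> list(term_name = , genes = )`.
#' @param background Character vector of gene symbols defining the testing
#'   universe; defaults to the union of all sets. Sets are harmonized to
#'   (intersected with) the background.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background = NULL) {
  if (length(sets) == 0) {
    p53_abort("a gene-set collection needs at least one set", "invalid_argument")
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    p53_abort("term ids must be unique and non-empty", "invalid_argument")
  }
  sets <- lapply(sets, function(s) {
    list(term_name = s$term_name %||% "", genes = unique(as.character(s$genes)))
  })
  if (is.null(background)) {
    background <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  } else {
    background <- sort(unique(as.character(background)))
    sets <- lapply(sets, function(s) {
      s$genes <- intersect(s$genes, background)
      s
    })
  }
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d background genes\n",
              length(x$sets), length(x$background)))
  invisible(x)
}

#' Read a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `term_id`, `description`, then one field per gene. Duplicate genes
#' within a set are deduplicated.
#'
#' @param path GMT file path.
#' @param background Optional universe overriding the default (union of
#'   all sets).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    p53_abort(sprintf("GMT file '%s' is empty", path), "parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    p53_abort(sprintf("GMT file '%s': line %d has fewer than 3 fields",
                      path, bad[1]), "parse_error")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  sets <- lapply(fields, function(f) list(term_name = f[2], genes = f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, background)
}

#' @param collection A [gene_set_collection()].
#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$term_name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' For each term a 2x2 table `[[k, n-k], [K-k, N-K-(n-k)]]` is built
#' (k = list genes in the term, n = list size after harmonization to the
#' background, K = background genes in the term, N = background size) and
#' tested with the uncorrected chi-squared. The enrichment score of a term
#' is `100 * k / n`, the percentage of the list annotated to it. Terms are
#' reported when `p_value < p_cutoff` AND
#' `enrichment_score_percent > score_cutoff_percent`, sorted by ascending
#' P with ties broken by term id. Terms producing a degenerate (zero
#' marginal) table are skipped with a warning.
#'
#' @param gene_list Character vector of gene symbols; symbols outside the
#'   background are dropped with a message.
#' @param collection A [gene_set_collection()].
#' @param p_cutoff P-value cutoff (default 0.05).
#' @param score_cutoff_percent Enrichment-score cutoff in percent
#'   (default 5).
#' @return A data frame with columns `term_id`, `term_name`, `k`, `n`,
#'   `K`, `N`, `chi2`, `p_value`, `enrichment_score_percent`.
#' @export
enrich <- function(gene_list, collection, p_cutoff = 0.05,
                   score_cutoff_percent = 5) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, collection$background)
  if (length(outside)) {
    message(sprintf("enrich: dropped %d gene(s) not in the background",
                    length(outside)))
  }
  genes <- intersect(gene_list, collection$background)
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), chi2 = numeric(), p_value = numeric(),
                      enrichment_score_percent = numeric(),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0) {
    warning("enrich: empty gene list after harmonization", call. = FALSE)
    return(empty)
  }
  n <- length(genes)
  N <- length(collection$background)
  rows <- lapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    K <- length(s$genes)
    k <- length(intersect(genes, s$genes))
    tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2, byrow = TRUE)
    res <- tryCatch(chi_squared_2x2(tab), p53screen_error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("enrich: term '%s' gives a degenerate table; skipped",
                      id), call. = FALSE)
      return(NULL)
    }
    data.frame(term_id = id, term_name = s$term_name, k = k, n = n, K = K,
               N = N, chi2 = res$statistic, p_value = res$p_value,
               enrichment_score_percent = 100 * k / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[out$p_value < p_cutoff &
             out$enrichment_score_percent > score_cutoff_percent, ,
             drop = FALSE]
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
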