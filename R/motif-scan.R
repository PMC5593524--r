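# p53 response-element scanner. The element is two RRRCWWGYYY half-sites
# (R = A/G, W = A/T, Y = C/T) separated by a 0-13 base spacer; only the 20
# half-site positions are informative, the spacer is never scored.

IUPAC_MATCH <- list(R = c("A", "G"), W = c("A", "T"), Y = c("C", "T"),
                    C = "C", G = "G")

#' The p53 response-element motif model
#'
#' @param spacer_min,spacer_max Inclusive spacer range in bases between
#'   the two half-sites (defaults 0 and 13, the canonical definition).
#' @return An object of class `motif_model` with elements `half_site`
#'   (the 10-symbol degenerate pattern `RRRCWWGYYY`), `spacer_range` and
#'   `informative_length` (20).
#' @export
p53_motif <- function(spacer_min = 0, spacer_max = 13) {
  if (!is_count(spacer_min) || !is_count(spacer_max) ||
      spacer_max < spacer_min) {
    p53_abort("spacer range must be non-negative integers with max >= min",
              "invalid_config")
  }
  structure(list(half_site = "RRRCWWGYYY",
                 spacer_range = c(spacer_min, spacer_max),
                 informative_length = 20L),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s [spacer %d-%d] %s\n", x$half_site,
              x$spacer_range[1], x$spacer_range[2], x$half_site))
  invisible(x)
}

# 1-based string positions of the 20 informative positions in a window of
# width 20 + spacer.
informative_positions <- function(spacer_length) {
  c(1:10, 10L + spacer_length + 1:10)
}

pattern_symbols <- function(model) {
  rep(strsplit(model$half_site, "")[[1]], 2L)
}

#' Score one candidate window against the consensus
#'
#' Counts, out of the 20 informative positions, how many bases satisfy
#' their degenerate consensus symbol. `N` bases match nothing.
#'
#' @param window Character scalar of length `20 + spacer_length` over
#'   A/C/G/T/N (case-insensitive).
#' @param spacer_length Spacer width in bases.
#' @param model A [p53_motif()].
#' @return Integer match count in 0-20.
#' @export
score_window <- function(window, spacer_length, model = p53_motif()) {
  window <- toupper(window)
  if (nchar(window) != 20L + spacer_length) {
    p53_abort(sprintf("window must have length %d (20 + spacer %d), got %d",
                      20L + spacer_length, spacer_length, nchar(window)),
              "invalid_argument")
  }
  chars <- strsplit(window, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    p53_abort("window may only contain A/C/G/T/N", "invalid_argument")
  }
  bases <- chars[informative_positions(spacer_length)]
  syms <- pattern_symbols(model)
  sum(vapply(seq_along(syms),
             function(i) bases[i] %in% IUPAC_MATCH[[syms[i]]],
             logical(1)))
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "")[[1]]),
                                 collapse = ""))
}

# Vectorized per-spacer scoring over all window starts of one sequence.
score_all_starts <- function(chars, spacer_length, model) {
  L <- length(chars)
  width <- 20L + spacer_length
  n_start <- L - width + 1L
  if (n_start < 1L) return(integer(0))
  syms <- pattern_symbols(model)
  offs <- informative_positions(spacer_length) - 1L
  score <- integer(n_start)
  starts <- seq_len(n_start)
  for (i in seq_along(syms)) {
    score <- score + (chars[starts + offs[i]] %in% IUPAC_MATCH[[syms[i]]])
  }
  score
}

#' Scan a sequence for p53 response elements
#'
#' Evaluates every combination of start position, spacer width (over the
#' model's range) and strand; reverse-strand windows are scored on the
#' reverse complement. Windows with at least `min_match` of 20 informative
#' positions matching are hits. Overlapping hits are pruned to a single
#' best hit per locus: highest match count, then smaller spacer, then
#' leftmost start, then the plus strand. Output is sorted by
#' (sequence id, start).
#'
#' @param sequence Character scalar (DNA), or a named character vector /
#'   `Biostrings::DNAStringSet` of sequences.
#' @param model A [p53_motif()].
#' @param min_match Minimum match count in 0-20 (default 15).
#' @param sequence_id Id used for a bare unnamed sequence.
#' @return A `motif_hits` data frame: `sequence_id`, `start` (0-based),
#'   `end` (exclusive; `end - start = 20 + spacer_length`), `strand`,
#'   `spacer_length`, `match_count`, `site_sequence` (spacer included,
#'   plus-strand orientation).
#' @export
scan_sites <- function(sequence, model = p53_motif(), min_match = 15,
                       sequence_id = "seq") {
  if (!is_count(min_match) || min_match > 20) {
    p53_abort("min_match must be an integer in [0, 20]", "invalid_argument")
  }
  seqs <- as_sequence_list(sequence, sequence_id)
  hits <- lapply(names(seqs), function(id) {
    scan_one(seqs[[id]], id, model, min_match)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- empty_hits()
  out <- out[order(out$sequence_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("motif_hits", "data.frame"))
}

as_sequence_list <- function(sequence, sequence_id) {
  if (inherits(sequence, "DNAStringSet")) {
    seqs <- as.character(sequence)
  } else if (is.character(sequence)) {
    seqs <- sequence
  } else {
    p53_abort("sequence must be character or a DNAStringSet",
              "invalid_argument")
  }
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1L) sequence_id
                   else paste0(sequence_id, "_", seq_along(seqs))
  }
  toupper(seqs)
}

empty_hits <- function() {
  data.frame(sequence_id = character(), start = integer(), end = integer(),
             strand = character(), spacer_length = integer(),
             match_count = integer(), site_sequence = character(),
             stringsAsFactors = FALSE)
}

scan_one <- function(seq, id, model, min_match) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 20L) return(NULL)
  rc_chars <- strsplit(revcomp(seq), "")[[1]]
  cand <- list()
  for (spacer in model$spacer_range[1]:model$spacer_range[2]) {
    width <- 20L + spacer
    if (width > L) break
    fwd <- score_all_starts(chars, spacer, model)
    rsc <- score_all_starts(rc_chars, spacer, model)
    n_start <- L - width + 1L
    # reverse-strand window ending at forward position e starts at
    # rc-position L - e + 1; map rc start j -> forward start L - width - j + 2
    rev_fwd <- rsc[n_start:1]
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") fwd else rev_fwd
      keep <- which(sc >= min_match)
      if (length(keep)) {
        cand[[length(cand) + 1L]] <- data.frame(
          sequence_id = id, start = keep - 1L, end = keep - 1L + width,
          strand = strand, spacer_length = spacer,
          match_count = as.integer(sc[keep]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  cand <- do.call(rbind, cand)
  kept <- prune_overlaps(cand)
  kept$site_sequence <- substring(seq, kept$start + 1L, kept$end)
  kept
}

# Greedy non-maximum suppression across strands: best-first by
# (match_count desc, spacer asc, start asc, '+' before '-'); a hit is kept
# only if it overlaps no already-kept hit.
prune_overlaps <- function(cand) {
  ord <- order(-cand$match_count, cand$spacer_length, cand$start,
               cand$strand != "+")
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  ends <- integer(0); starts <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s < ends & e > starts)) {
      kept[i] <- TRUE
      starts <- c(starts, s); ends <- c(ends, e)
    }
  }
  cand[kept, , drop = FALSE]
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("<motif_hits> %d site(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Scan sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param ... Passed to [scan_sites()].
#' @return A `motif_hits` data frame over all records in the file.
#' @export
scan_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  scan_sites(seqs, ...)
}

#' Reporter-assay mutagenesis of a response element
#'
#' Reproduces the site-directed mutagenesis used to kill a response
#' element in reporter constructs: of the 20 informative (1-based,
#' spacer-skipped) positions, the 4th and 14th (consensus C) and the 7th
#' and 17th (consensus G) are set to T. The spacer is untouched. The
#' mutated site never scores higher than the input, and scores strictly
#' lower whenever the input matched the consensus at any mutated
#' position.
#'
#' @param site_sequence Full site (two half-sites plus spacer).
#' @param spacer_length Spacer width in bases.
#' @return The mutated site sequence (same length).
#' @export
mutate_site <- function(site_sequence, spacer_length) {
  site_sequence <- toupper(site_sequence)
  if (nchar(site_sequence) != 20L + spacer_length) {
    p53_abort(sprintf("site must have length %d (20 + spacer %d), got %d",
                      20L + spacer_length, spacer_length,
                      nchar(site_sequence)), "invalid_argument")
  }
  chars <- strsplit(site_sequence, "")[[1]]
  pos <- informative_positions(spacer_length)[c(4L, 7L, 14L, 17L)]
  chars[pos] <- "T"
  paste(chars, collapse = "")
}
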