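# Independent oracles, written as literal re-implementations so they stay
# decoupled from the package's code paths.

# --- motif scanning ---------------------------------------------------------

oracle_allowed <- list(R = c("A", "G"), W = c("A", "T"), Y = c("C", "T"),
                       C = "C", G = "G")
oracle_pattern <- rep(c("R", "R", "R", "C", "W", "W", "G", "Y", "Y", "Y"), 2)

oracle_score <- function(chars, start, spacer) {
  # start is 1-based; returns matches over the 20 informative positions
  idx <- c(start + 0:9, start + 10 + spacer + 0:9)
  n <- 0L
  for (i in 1:20) {
    if (chars[idx[i]] %in% oracle_allowed[[oracle_pattern[i]]]) n <- n + 1L
  }
  n
}

oracle_revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

# literal enumeration of every (start, spacer, strand) window, then the
# documented pruning rule re-implemented from scratch
oracle_scan <- function(seq, min_match = 15, spacer_range = c(0, 13),
                        id = "seq") {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  rc <- oracle_revcomp_chars(chars)
  rows <- list()
  for (spacer in spacer_range[1]:spacer_range[2]) {
    width <- 20 + spacer
    if (width > L) next
    for (start in 1:(L - width + 1)) {
      sp <- oracle_score(chars, start, spacer)
      if (sp >= min_match) {
        rows[[length(rows) + 1]] <- data.frame(
          sequence_id = id, start = start - 1L, end = start - 1L + width,
          strand = "+", spacer_length = spacer, match_count = sp,
          stringsAsFactors = FALSE)
      }
      # minus strand: window [start, start+width-1] read on the reverse
      # complement corresponds to rc positions (L - end + 1) ...
      rc_start <- L - (start + width - 1) + 1
      sm <- oracle_score(rc, rc_start, spacer)
      if (sm >= min_match) {
        rows[[length(rows) + 1]] <- data.frame(
          sequence_id = id, start = start - 1L, end = start - 1L + width,
          strand = "-", spacer_length = spacer, match_count = sm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer_length = integer(), match_count = integer(),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, rows)
  ord <- order(-cand$match_count, cand$spacer_length, cand$start,
               cand$strand != "+")
  cand <- cand[ord, , drop = FALSE]
  kept <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(kept)) {
      prev <- cand[kept, , drop = FALSE]
      if (any(cand$start[i] < prev$end & cand$end[i] > prev$start)) ok <- FALSE
    }
    kept[i] <- ok
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- dual screen ------------------------------------------------------------

# literal re-evaluation of both screening equations and thresholds on a
# probe-level matrix; returns the per-screen gene hit sets
oracle_screen <- function(values, gene_of, signal_ids, control_ids,
                          fold_threshold, alpha = 0.05) {
  genes <- character(0)
  for (g in unique(gene_of)) {
    pass <- FALSE
    for (pr in rownames(values)[gene_of == g]) {
      sig <- values[pr, signal_ids]
      ctl <- values[pr, control_ids]
      if (var(c(sig, ctl)) == 0) next
      fold <- median(sig) / max(ctl)
      if (var(sig) == 0 && var(ctl) == 0) {
        p <- if (mean(sig) == mean(ctl)) 1 else 0
      } else if (var(sig) == 0 || var(ctl) == 0) {
        p <- t.test(sig, ctl, var.equal = FALSE)$p.value
      } else {
        pooled <- var.test(sig, ctl)$p.value >= 0.05
        p <- t.test(sig, ctl, var.equal = pooled)$p.value
      }
      if (fold > fold_threshold && p < alpha) pass <- TRUE
    }
    if (pass) genes <- c(genes, g)
  }
  sort(genes)
}

# --- survival ---------------------------------------------------------------

# product-limit estimator from first principles
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(0); at_risk <- integer(0)
  for (t in ut) {
    n_t <- sum(times >= t)
    d_t <- sum(times == t & events == 1)
    s <- s * (1 - d_t / n_t)
    surv <- c(surv, s)
    at_risk <- c(at_risk, n_t)
  }
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  list(event_times = ut, survival_prob = surv, at_risk = at_risk,
       median_survival = med)
}

# two-group log-rank chi-squared from first principles
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ut <- sort(unique(times[events == 1]))
  o1 <- 0; ex1 <- 0; v <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & grp == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp == 1)
    o1 <- o1 + d1
    ex1 <- ex1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - ex1)^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# --- Mann-Whitney -----------------------------------------------------------

# exact two-sided P by full enumeration of group assignments
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  us <- apply(combos, 2, function(ix) {
    sum(rank(pooled)[ix]) - n * (n + 1) / 2
  })
  center <- n * m / 2
  mean(abs(us - center) >= abs(u_obs - center))
}

# --- misc -------------------------------------------------------------------

table1_hits <- function(cfg = screen_config()) {
  t1 <- candidate_table()
  list(
    table = t1,
    hits1 = table_to_hits(
      data.frame(gene = t1$gene, fold = t1$fold1, p_value = t1$p1),
      "screen1", cfg),
    hits2 = table_to_hits(
      data.frame(gene = t1$gene, fold = t1$fold2, p_value = t1$p2),
      "screen2", cfg))
}
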