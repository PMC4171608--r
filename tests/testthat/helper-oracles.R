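# Independent oracles, kept deliberately naive: brute-force scanners and
# enumerations that share no code path with the implementation.

# Every maximal perfect tandem run, found by testing each (start, period)
# pair directly; composite motifs dropped so runs are reported at their
# smallest period, runs with N dropped.
oracle_repeat_scan <- function(sequence, chrom, min_unit = 1L, max_unit = 6L,
                               min_length = 10L) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (k in min_unit:max_unit) {
    for (s in seq_len(n)) {
      # extend the period-k run starting at s
      e <- s + k - 1L
      if (e > n) next
      while (e + 1L <= n && ch[e + 1L] == ch[e + 1L - k]) e <- e + 1L
      len <- e - s + 1L
      if (len < 2L * k || len < min_length) next
      # maximal on the left?
      if (s > 1L && ch[s - 1L] == ch[s - 1L + k]) next
      motif <- paste(ch[s:(s + k - 1L)], collapse = "")
      # primitive motif?
      comp <- FALSE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L &&
            motif == strrep(substr(motif, 1L, d), k / d)) comp <- TRUE
      }
      if (comp) next
      if (grepl("N", paste(ch[s:e], collapse = ""), fixed = TRUE)) next
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom, start = s - 1L, end = e, motif = motif,
                   ref_length = len, stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), motif = character(),
                      ref_length = integer()))
  }
  out <- out[order(out$start, nchar(out$motif)), ]
  rownames(out) <- NULL
  out
}

# Exact two-sided Fisher p by direct lchoose enumeration for one table.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- seq.int(max(0L, c1 - r2), min(r1, c1))
  pr <- exp(lchoose(r1, supp) + lchoose(r2, c1 - supp) -
              lchoose(r1 + r2, c1))
  min(1, sum(pr[pr <= pr[supp == a] * (1 + 1e-7)]))
}

# Same, vectorised over the whole margin family via an outer comparison.
oracle_fisher_family <- function(r1, r2, c1) {
  supp <- seq.int(max(0L, c1 - r2), min(r1, c1))
  pr <- exp(lchoose(r1, supp) + lchoose(r2, c1 - supp) -
              lchoose(r1 + r2, c1))
  pmin(1, colSums(outer(pr, pr * (1 + 1e-7), "<=") * pr))
}

# Textbook BH step-up: explicit loop over sorted p-values.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k_max <- 0L
  for (k in seq_len(m)) {
    if (p[o[k]] <= k / m * q) k_max <- k
  }
  rej <- rep(FALSE, m)
  if (k_max > 0L) rej[o[seq_len(k_max)]] <- TRUE
  rej
}

# Exhaustive-threshold ROC: confusion-matrix counting at every candidate
# cutoff, max Youden's J, ties to higher specificity then higher cutoff.
oracle_roc <- function(fractions, is_positive) {
  cand <- c(sort(unique(fractions)), max(fractions) + 1)
  best <- NULL
  for (t in cand) {
    tp <- sum(fractions >= t & is_positive)
    fn <- sum(fractions < t & is_positive)
    tn <- sum(fractions < t & !is_positive)
    fp <- sum(fractions >= t & !is_positive)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(spec - best$spec) <= 1e-12 &&
           t > best$t)) {
      best <- list(t = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# All-pairs nearest gap distance (closed intervals, overlap -> 0).
oracle_nearest <- function(loci, track) {
  vapply(seq_len(nrow(loci)), function(i) {
    same <- track[track$chrom == loci$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return(NA_real_)
    d <- pmax(0, pmax(same$start - loci$end[i], loci$start[i] - same$end))
    min(d)
  }, numeric(1L))
}
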