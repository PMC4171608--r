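# Case/control genotype association: cohort-level QC filters, predominant
# (consensus) control genotype, exact two-sided Fisher tests per
# (locus, genotype) hypothesis, relative risk, and the Benjamini-Hochberg
# signature cutoff with the q* = 1/X rule.

#' Apply cohort-level inclusion filters to a genotype table
#'
#' Samples with fewer than `min_loci_per_sample` called loci are dropped
#' (uniformity-of-coverage rule); loci called in fewer than
#' `min_samples_per_locus` samples of any cohort are dropped.
#'
#' @param table Long-format cohort genotype table (see [genotype_cohort()] or
#'   [simulate_cohort_genotypes()]).
#' @param min_loci_per_sample Minimum called loci per retained sample
#'   (default 15000, the exome-scale inclusion rule; scale down for small
#'   synthetic cohorts).
#' @param min_samples_per_locus Minimum samples in which a locus must be
#'   called, in every cohort (default 10).
#' @return The filtered table, with a filter report (`samples_dropped`,
#'   `loci_dropped` and counts) attached as `attr(x, "filter_report")`.
#' @export
apply_cohort_filters <- function(table, min_loci_per_sample = 15000L,
                                 min_samples_per_locus = 10L) {
  stopifnot(length(unique(table$cohort)) >= 2L)
  per_sample <- called_loci_per_sample(table)
  keep_samples <- names(per_sample)[per_sample >= min_loci_per_sample]
  dropped_samples <- setdiff(names(per_sample), keep_samples)
  x <- table[table$sample_id %in% keep_samples, ]

  called <- x[x$status == "called", ]
  counts <- base::table(called$locus_id, called$cohort)
  cohorts <- unique(x$cohort)
  all_loci <- unique(x$locus_id)
  ok <- rep(FALSE, length(all_loci))
  names(ok) <- all_loci
  if (nrow(counts) > 0L) {
    present <- rownames(counts)
    enough <- apply(counts[, cohorts, drop = FALSE] >= min_samples_per_locus,
                    1L, all)
    ok[present] <- enough
  }
  keep_loci <- names(ok)[ok]
  dropped_loci <- setdiff(all_loci, keep_loci)
  x <- x[x$locus_id %in% keep_loci, ]
  attr(x, "filter_report") <- list(
    samples_dropped = dropped_samples,
    n_samples_dropped = length(dropped_samples),
    loci_dropped = dropped_loci,
    n_loci_dropped = length(dropped_loci)
  )
  x
}

#' Predominant (consensus) genotype at a locus in the control cohort
#'
#' The modal genotype among called control samples. Ties are broken toward
#' the genotype homozygous for the reference tract length when `ref_length`
#' is supplied, then toward the numerically smallest allele pair.
#'
#' @param table Cohort genotype table.
#' @param locus Locus id.
#' @param control_label Cohort label of the control population.
#' @param ref_length Optional reference tract length used in the tie-break.
#' @return Genotype string `"a/b"`.
#' @export
predominant_genotype <- function(table, locus, control_label,
                                 ref_length = NULL) {
  g <- table$genotype[table$locus_id == locus &
                        table$cohort == control_label &
                        table$status == "called"]
  if (length(g) == 0L) {
    stop("no called control genotypes at locus ", locus)
  }
  tab <- base::table(g)
  modal <- names(tab)[tab == max(tab)]
  if (length(modal) == 1L) return(modal)
  if (!is.null(ref_length)) {
    ref_gt <- paste0(ref_length, "/", ref_length)
    if (ref_gt %in% modal) return(ref_gt)
  }
  pairs <- do.call(rbind, lapply(strsplit(modal, "/", fixed = TRUE),
                                 as.integer))
  modal[order(pairs[, 1L], pairs[, 2L])][1L]
}

#' Exact two-sided Fisher p-values for a hypergeometric margin family
#'
#' Computes, for every 2x2 table with case margin `r1`, control margin `r2`
#' and first-column margin `c1`, the exact two-sided p-value: the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (with the conventional 1e-7 relative tolerance for ties).
#'
#' @param r1,r2 Row margins (cases, controls).
#' @param c1 First-column margin (samples carrying the genotype).
#' @return Named list: `support` (possible values of cell `a`) and `p`
#'   (two-sided p for each value of `a`).
#' @export
fisher_family_pvalues <- function(r1, r2, c1) {
  support <- seq.int(max(0L, c1 - r2), min(r1, c1))
  probs <- stats::dhyper(support, r1, r2, c1)
  ord <- order(probs)
  sorted <- probs[ord]
  csum <- cumsum(sorted)
  idx <- findInterval(probs * (1 + 1e-7), sorted)
  p <- pmin(csum[idx], 1)
  list(support = support, p = p)
}

#' Exact two-sided Fisher test for one 2x2 table
#'
#' @param a,b,c,d Cell counts: case-with-genotype, case-without,
#'   control-with, control-without.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  fam <- fisher_family_pvalues(a + b, c + d, a + c)
  fam$p[match(a, fam$support)]
}

#' Test one (locus, genotype) hypothesis between cohorts
#'
#' Builds the 2x2 contingency table of carrier counts over callable
#' (`status == "called"`) samples only, computes the exact two-sided Fisher
#' p-value and the relative risk
#' \eqn{RR = (a/(a+b)) / (c/(c+d))}.
#' When no control carries the genotype (`c == 0`), `relative_risk` is
#' `Inf` and the Haldane-Anscombe-corrected companion (`+0.5` to every cell)
#' in `relative_risk_haldane` should be used for ranking.
#'
#' @param table Cohort genotype table (post [apply_cohort_filters()]).
#' @param locus Locus id.
#' @param genotype Genotype string to test.
#' @param case_label,control_label Cohort labels.
#' @param predominant Optional predominant control genotype to record.
#' @return One-row `data.frame`: `locus_id`, `genotype`, `a`, `b`, `c`, `d`,
#'   `p_value`, `relative_risk`, `relative_risk_haldane`,
#'   `predominant_control_genotype`. Cohorts with zero callable samples give
#'   `p_value = NA` (sentinel; the hypothesis is excluded downstream).
#' @export
fisher_association <- function(table, locus, genotype, case_label,
                               control_label, predominant = NA_character_) {
  sub <- table[table$locus_id == locus & table$status == "called", ]
  cases <- sub[sub$cohort == case_label, ]
  controls <- sub[sub$cohort == control_label, ]
  a <- sum(cases$genotype == genotype)
  b <- nrow(cases) - a
  c_ <- sum(controls$genotype == genotype)
  d <- nrow(controls) - c_
  if (nrow(cases) == 0L || nrow(controls) == 0L) {
    p <- NA_real_; rr <- NA_real_; rrh <- NA_real_
  } else {
    p <- fisher_exact(a, b, c_, d)
    rr <- if (c_ == 0L) Inf else (a / (a + b)) / (c_ / (c_ + d))
    rrh <- ((a + 0.5) / (a + b + 1)) / ((c_ + 0.5) / (c_ + d + 1))
  }
  data.frame(locus_id = locus, genotype = genotype,
             a = a, b = b, c = c_, d = d,
             p_value = p, relative_risk = rr, relative_risk_haldane = rrh,
             predominant_control_genotype = predominant,
             stringsAsFactors = FALSE)
}

#' Test every non-predominant genotype at every locus
#'
#' For each locus the predominant control genotype is determined and every
#' other genotype observed among called samples (in either cohort) is tested
#' against "not that genotype" with [fisher_association()].
#'
#' @param table Cohort genotype table (post [apply_cohort_filters()]).
#' @param case_label,control_label Cohort labels.
#' @param catalog Optional catalog supplying `ref_length` for the
#'   predominant-genotype tie-break.
#' @return `data.frame` of association rows (see [fisher_association()]).
#' @export
associate_cohorts <- function(table, case_label, control_label,
                              catalog = NULL) {
  called <- table[table$status == "called", ]
  loci <- sort(unique(called$locus_id))
  ref_lengths <- NULL
  if (!is.null(catalog)) {
    ref_lengths <- setNames(catalog$ref_length, catalog$locus_id)
  }
  rows <- vector("list", 0L)
  for (lid in loci) {
    sub <- called[called$locus_id == lid, ]
    if (!any(sub$cohort == control_label)) next
    rl <- if (!is.null(ref_lengths)) unname(ref_lengths[lid]) else NULL
    pred <- predominant_genotype(table, lid, control_label, ref_length = rl)
    tested <- setdiff(sort(unique(sub$genotype)), pred)
    for (g in tested) {
      rows[[length(rows) + 1L]] <-
        fisher_association(table, lid, g, case_label, control_label,
                           predominant = pred)
    }
  }
  if (length(rows) == 0L) return(empty_associations())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_associations <- function() {
  data.frame(locus_id = character(), genotype = character(),
             a = integer(), b = integer(), c = integer(), d = integer(),
             p_value = numeric(), relative_risk = numeric(),
             relative_risk_haldane = numeric(),
             predominant_control_genotype = character(),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up at a data-driven level
#'
#' Returns the indices of hypotheses rejected by the BH step-up procedure at
#' level `q`: with sorted p-values \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' find the largest \eqn{k} with \eqn{p_{(k)} \le (k/m) q} and reject all
#' hypotheses with \eqn{p \le p_{(k)}}.
#'
#' @param p Numeric vector of p-values.
#' @param q FDR level.
#' @return Logical vector marking rejected hypotheses.
#' @export
bh_reject <- function(p, q) {
  m <- length(p)
  if (m == 0L) return(logical(0L))
  o <- order(p)
  sorted <- p[o]
  ok <- sorted <= (seq_len(m) / m) * q
  if (!any(ok)) return(rep(FALSE, m))
  thr <- sorted[max(which(ok))]
  p <= thr
}

#' Assemble the FDR-controlled CAML signature
#'
#' Candidate hypotheses are those with raw `p_value <= alpha`. The BH step-up
#' procedure is applied over all tested hypotheses at the data-driven level
#' `q* = 1/X`, where `X` is the number of tested hypotheses with p-value
#' strictly below 1 (so that, in expectation, fewer than one signature member
#' is a false discovery). Signature members must pass both the `alpha` filter
#' and the BH cutoff.
#'
#' @param associations Association rows from [associate_cohorts()].
#' @param alpha Per-hypothesis significance level (default 0.01).
#' @param label Signature label, e.g. `"case-vs-control"`.
#' @return An object of class `caml_signature`: list with `label`,
#'   `caml_genotypes` (association rows of members), `alpha` and `fdr_rule`
#'   (`X`, `q_star`, `m`, `bh_threshold`).
#' @export
bh_signature_cutoff <- function(associations, alpha = 0.01,
                                label = "case-vs-control") {
  assoc <- associations[!is.na(associations$p_value), , drop = FALSE]
  m <- nrow(assoc)
  X <- sum(assoc$p_value < 1)
  q_star <- if (X > 0L) 1 / X else 0
  if (m == 0L || X == 0L) {
    members <- assoc[0L, , drop = FALSE]
    bh_thr <- NA_real_
  } else {
    rejected <- bh_reject(assoc$p_value, q_star)
    pass <- rejected & assoc$p_value <= alpha
    members <- assoc[pass, , drop = FALSE]
    bh_thr <- if (any(rejected)) max(assoc$p_value[rejected]) else NA_real_
  }
  rownames(members) <- NULL
  structure(list(label = label,
                 caml_genotypes = members,
                 alpha = alpha,
                 fdr_rule = list(X = X, q_star = q_star, m = m,
                                 bh_threshold = bh_thr)),
            class = "caml_signature")
}

#' @export
print.caml_signature <- function(x, ...) {
  cat("CAML signature:", x$label, "\n")
  cat("  members:", nrow(x$caml_genotypes),
      sprintf("(alpha = %g, q* = 1/%d = %.4g over %d hypotheses)\n",
              x$alpha, x$fdr_rule$X, x$fdr_rule$q_star, x$fdr_rule$m))
  if (nrow(x$caml_genotypes) > 0L) {
    utils::head(x$caml_genotypes[, c("locus_id", "genotype", "p_value",
                                     "relative_risk")], 10L) |> print()
  }
  invisible(x)
}
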