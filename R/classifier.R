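# Signature-based sample classification: per-sample detection fraction over
# callable signature loci, ROC cutoff selection (Youden's J), grade-vs-grade
# comparisons, and tumor/germline concordance.

#' Score samples by signature detection fraction
#'
#' For each sample, `detectable` counts signature loci with a called genotype
#' in that sample, `matched` counts those whose called genotype equals the
#' signature genotype, and `fraction = matched / detectable` is the
#' classification score. Samples with no callable signature locus are flagged
#' `unscorable` (fraction `NA`) and excluded from ROC analysis.
#'
#' @param table Cohort genotype table.
#' @param signature A `caml_signature` (see [bh_signature_cutoff()]), or a
#'   `data.frame` with columns `locus_id` and `genotype`.
#' @return `data.frame`: `sample_id`, `true_label` (the cohort label),
#'   `detectable`, `matched`, `fraction`, `unscorable`.
#' @export
score_samples <- function(table, signature) {
  sig <- signature_members(signature)
  if (nrow(sig) == 0L) stop("signature is empty")
  sub <- table[table$locus_id %in% sig$locus_id, ]
  sig_gt <- setNames(sig$genotype, sig$locus_id)
  samples <- unique(table$sample_id)
  labels <- table$cohort[match(samples, table$sample_id)]
  out <- data.frame(sample_id = samples, true_label = labels,
                    detectable = 0L, matched = 0L,
                    stringsAsFactors = FALSE)
  called <- sub[sub$status == "called", ]
  if (nrow(called) > 0L) {
    det <- base::table(called$sample_id)
    out$detectable <- as.integer(det[out$sample_id])
    out$detectable[is.na(out$detectable)] <- 0L
    hit <- called[called$genotype == sig_gt[called$locus_id], ]
    mat <- base::table(hit$sample_id)
    out$matched <- as.integer(mat[out$sample_id])
    out$matched[is.na(out$matched)] <- 0L
  }
  out$fraction <- ifelse(out$detectable > 0L,
                         out$matched / out$detectable, NA_real_)
  out$unscorable <- out$detectable == 0L
  out
}

signature_members <- function(signature) {
  if (inherits(signature, "caml_signature")) {
    sig <- signature$caml_genotypes
  } else {
    sig <- signature
  }
  stopifnot(all(c("locus_id", "genotype") %in% names(sig)))
  if (anyDuplicated(sig$locus_id)) {
    stop("signature contains more than one genotype for a locus")
  }
  sig
}

#' Detection-fraction histogram
#'
#' Bins scorable samples' detection fractions and reports the percentage of
#' samples per bin, per true label (the familiar fraction-of-signature
#' histogram).
#'
#' @param results Output of [score_samples()].
#' @param bin_width Bin width on the fraction axis (default 0.1).
#' @return `data.frame`: `true_label`, `bin_low`, `bin_high`,
#'   `percent_samples`. Bins are `(low, high]` with 0 included in the first.
#' @export
detection_histogram <- function(results, bin_width = 0.1) {
  res <- results[!results$unscorable, ]
  breaks <- seq(0, 1, by = bin_width)
  rows <- lapply(split(res, res$true_label), function(g) {
    cuts <- cut(g$fraction, breaks = breaks, include.lowest = TRUE)
    tab <- base::table(cuts)
    data.frame(true_label = g$true_label[1L],
               bin_low = breaks[-length(breaks)],
               bin_high = breaks[-1L],
               percent_samples = 100 * as.numeric(tab) / nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC cutoff on detection fractions
#'
#' Evaluates every observed fraction (plus an all-negative threshold) as the
#' cutoff `fraction >= t`, computes sensitivity and specificity against the
#' true labels, and picks the threshold maximizing Youden's
#' \eqn{J = sensitivity + specificity - 1}; ties are broken toward the higher
#' specificity (equivalently the higher cutoff).
#'
#' @param results Output of [score_samples()] with both classes present among
#'   scorable samples.
#' @param positive,negative Labels of the positive (case) and negative class.
#' @return List: `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   `roc_points` (`data.frame` of threshold, sensitivity, specificity, J),
#'   and `results` with a `predicted_label` / `predicted_positive` column
#'   (`fraction >= cutoff`).
#' @export
roc_cutoff <- function(results, positive, negative) {
  res <- results[!results$unscorable &
                   results$true_label %in% c(positive, negative), ]
  y <- res$true_label == positive
  if (!any(y) || all(y)) {
    stop("ROC undefined: need scorable samples from both classes")
  }
  f <- res$fraction
  thresholds <- sort(unique(f))
  thresholds <- c(thresholds, max(thresholds) + 1)  # all-negative extreme
  sens <- spec <- j <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- f >= thresholds[i]
    sens[i] <- sum(pred & y) / sum(y)
    spec[i] <- sum(!pred & !y) / sum(!y)
    j[i] <- sens[i] + spec[i] - 1
  }
  best <- which(j == max(j))
  best <- best[which.max(spec[best] + thresholds[best] * 1e-12)]
  cutoff <- thresholds[best]
  res$predicted_positive <- res$fraction >= cutoff
  res$predicted_label <- ifelse(res$predicted_positive, positive, negative)
  list(cutoff = cutoff, sensitivity = sens[best], specificity = spec[best],
       youden_j = j[best],
       roc_points = data.frame(threshold = thresholds, sensitivity = sens,
                               specificity = spec, youden_j = j),
       results = res)
}

#' Grade-vs-grade signature comparison
#'
#' Applies [score_samples()] and [roc_cutoff()] with one case cohort as the
#' positive class and another as the negative class (e.g. high-grade vs
#' lower-grade disease), the design used to ask whether a signature carries
#' grade information.
#'
#' @param table_pos,table_neg Genotype tables of the two cohorts (each may
#'   contain one cohort; they are concatenated).
#' @param signature Signature to score.
#' @param positive,negative Cohort labels for the two classes.
#' @return List with `scores` (per-sample results), `roc` (see
#'   [roc_cutoff()]) and `histogram` (see [detection_histogram()]).
#' @export
cross_signature_comparison <- function(table_pos, table_neg, signature,
                                       positive, negative) {
  combined <- rbind(as.data.frame(table_pos), as.data.frame(table_neg))
  scores <- score_samples(combined, signature)
  roc <- roc_cutoff(scores, positive, negative)
  list(scores = scores, roc = roc, histogram = detection_histogram(scores))
}

#' Tumor/germline signature concordance
#'
#' For matched sample pairs (same `sample_id` in both tables), reports the
#' per-signature-locus genotype agreement rate and a two-sided Fisher exact
#' test of the signature-genotype carrier frequency between compartments.
#' Loci with `p < flag_alpha` are flagged as discordant between compartments.
#'
#' @param germline,tumor Genotype tables for the two compartments.
#' @param signature Signature whose loci are examined.
#' @param flag_alpha Significance level for flagging (default 0.01).
#' @return `data.frame`: `locus_id`, `genotype`, `n_pairs` (pairs called in
#'   both compartments), `concordance`, `p_value`, `flagged`; overall
#'   concordance attached as `attr(x, "overall_concordance")`.
#' @export
tumor_germline_concordance <- function(germline, tumor, signature,
                                       flag_alpha = 0.01) {
  sig <- signature_members(signature)
  shared <- intersect(unique(germline$sample_id), unique(tumor$sample_id))
  if (length(shared) == 0L) stop("no matched sample pairs")
  g <- germline[germline$sample_id %in% shared &
                  germline$locus_id %in% sig$locus_id &
                  germline$status == "called", ]
  t_ <- tumor[tumor$sample_id %in% shared &
                tumor$locus_id %in% sig$locus_id &
                tumor$status == "called", ]
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    lid <- sig$locus_id[i]; sgt <- sig$genotype[i]
    gg <- g[g$locus_id == lid, ]
    tt <- t_[t_$locus_id == lid, ]
    both <- intersect(gg$sample_id, tt$sample_id)
    ggt <- gg$genotype[match(both, gg$sample_id)]
    tgt <- tt$genotype[match(both, tt$sample_id)]
    conc <- if (length(both)) mean(ggt == tgt) else NA_real_
    # carrier-frequency contrast between compartments at this locus
    a <- sum(ggt == sgt); b <- length(both) - a
    c_ <- sum(tgt == sgt); d <- length(both) - c_
    p <- if (length(both)) fisher_exact(a, b, c_, d) else NA_real_
    data.frame(locus_id = lid, genotype = sgt, n_pairs = length(both),
               concordance = conc, p_value = p,
               flagged = !is.na(p) & p < flag_alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_tot <- sum(out$n_pairs)
  attr(out, "overall_concordance") <-
    if (n_tot > 0L) sum(out$concordance * out$n_pairs, na.rm = TRUE) /
      sum(out$n_pairs[!is.na(out$concordance)]) else NA_real_
  out
}
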