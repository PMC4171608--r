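# signature_classifier: detection fractions, ROC cutoff, grade-vs-grade,
# tumor/germline concordance

sig2 <- data.frame(locus_id = c("L1", "L2"), genotype = c("12/14", "15/15"),
                   stringsAsFactors = FALSE)

test_that("detection fractions count matches over callable signature loci", {
  tab <- rbind(
    gt_rows("L1", "GBM", "12/14", 1L, prefix = "s"),
    gt_rows("L2", "GBM", "15/15", 1L, prefix = "s"),
    gt_rows("L1", "GBM", "12/14", 1L, prefix = "t"),
    gt_rows("L2", "GBM", "14/14", 1L, prefix = "t"),
    gt_rows("L1", "GBM", NA_character_, 1L, status = "low_coverage",
            prefix = "u"),
    gt_rows("L2", "GBM", "14/14", 1L, prefix = "u"),
    gt_rows("L1", "GBM", NA_character_, 1L, status = "no_reads",
            prefix = "v"),
    gt_rows("L2", "GBM", NA_character_, 1L, status = "low_coverage",
            prefix = "v")
  )
  res <- score_samples(tab, sig2)
  expect_equal(res$fraction[res$sample_id == "s001"], 1)
  expect_equal(res$fraction[res$sample_id == "t001"], 0.5)
  expect_equal(res$fraction[res$sample_id == "u001"], 0)
  expect_equal(res$detectable[res$sample_id == "u001"], 1L)
  expect_true(res$unscorable[res$sample_id == "v001"])
  # invariant under signature reordering
  res_rev <- score_samples(tab, sig2[2:1, ])
  expect_equal(res[order(res$sample_id), ], res_rev[order(res_rev$sample_id), ],
               ignore_attr = TRUE)
})

test_that("scoring a planted-effect cohort gives the expected means", {
  set.seed(31)
  n_sig <- 25L
  loci <- sprintf("S%02d", seq_len(n_sig))
  sig <- data.frame(locus_id = loci, genotype = "12/14")
  build <- function(cohort, n, carry_p) {
    do.call(rbind, lapply(loci, function(l) {
      carried <- stats::rbinom(n, 1L, carry_p) == 1L
      r <- gt_rows(l, cohort, "12/14", n)
      r$genotype[!carried] <- "14/14"
      r
    }))
  }
  tab <- rbind(build("CASE", 100L, 0.8), build("CTRL", 100L, 0.2))
  res <- score_samples(tab, sig)
  expect_equal(mean(res$fraction[res$true_label == "CASE"]), 0.8,
               tolerance = 0.03)
  expect_equal(mean(res$fraction[res$true_label == "CTRL"]), 0.2,
               tolerance = 0.03)
  roc <- roc_cutoff(res, "CASE", "CTRL")
  expect_gte(roc$sensitivity, 0.85)
  expect_gte(roc$specificity, 0.85)
})

test_that("roc_cutoff equals exhaustive-threshold enumeration", {
  # worked example
  res <- data.frame(sample_id = paste0("s", 1:6),
                    true_label = rep(c("P", "N"), each = 3L),
                    detectable = 10L, matched = 5L,
                    fraction = c(0.8, 0.7, 0.4, 0.3, 0.2, 0.6),
                    unscorable = FALSE)
  roc <- roc_cutoff(res, "P", "N")
  want <- oracle_roc(res$fraction, res$true_label == "P")
  expect_equal(roc$cutoff, want$t)
  expect_equal(roc$sensitivity, want$sens)
  expect_equal(roc$specificity, want$spec)

  # random score sets, including ties
  set.seed(32)
  for (i in 1:25) {
    n <- sample(6:60, 1L)
    y <- c(TRUE, FALSE, stats::runif(n - 2L) < 0.5)
    f <- round(stats::runif(n), sample(c(1L, 2L), 1L))
    res <- data.frame(sample_id = paste0("s", seq_len(n)),
                      true_label = ifelse(y, "P", "N"),
                      detectable = 10L, matched = 1L, fraction = f,
                      unscorable = FALSE)
    roc <- roc_cutoff(res, "P", "N")
    want <- oracle_roc(f, y)
    expect_equal(roc$cutoff, want$t)
    expect_equal(roc$sensitivity, want$sens)
    expect_equal(roc$specificity, want$spec)
    # every ROC point equals direct confusion-matrix counting
    for (r in sample(nrow(roc$roc_points), 5L)) {
      t <- roc$roc_points$threshold[r]
      expect_equal(roc$roc_points$sensitivity[r],
                   sum(f >= t & y) / sum(y))
      expect_equal(roc$roc_points$specificity[r],
                   sum(f < t & !y) / sum(!y))
    }
  }
})

test_that("perfect separation gives sens = spec = 1; degenerate input errors", {
  res <- data.frame(sample_id = paste0("s", 1:20),
                    true_label = rep(c("P", "N"), each = 10L),
                    detectable = 10L, matched = 5L,
                    fraction = rep(c(0.9, 0.1), each = 10L),
                    unscorable = FALSE)
  roc <- roc_cutoff(res, "P", "N")
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
  expect_equal(roc$cutoff, 0.9)
  expect_true(all(roc$results$predicted_label ==
                    roc$results$true_label))
  expect_error(roc_cutoff(res[res$true_label == "P", ], "P", "N"), "ROC")
})

test_that("label permutation drives Youden's J toward zero", {
  set.seed(33)
  js <- replicate(40L, {
    f <- stats::runif(60L)
    y <- sample(rep(c(TRUE, FALSE), each = 30L))
    res <- data.frame(sample_id = paste0("s", 1:60),
                      true_label = ifelse(y, "P", "N"),
                      detectable = 1L, matched = 1L, fraction = f,
                      unscorable = FALSE)
    roc_cutoff(res, "P", "N")$youden_j
  })
  # optimised J is biased above 0 under the null, but stays small
  expect_lt(mean(js), 0.35)
  expect_gt(min(js), -1e-12)
})

test_that("cross-cohort comparison runs the same machinery per grade", {
  set.seed(34)
  build <- function(cohort, carry_p) {
    do.call(rbind, lapply(sig2$locus_id, function(l) {
      g <- sig2$genotype[sig2$locus_id == l]
      r <- gt_rows(l, cohort, g, 40L)
      r$genotype[stats::runif(40L) > carry_p] <- "9/9"
      r
    }))
  }
  cmp <- cross_signature_comparison(build("GBM", 0.9), build("LGG", 0.1),
                                    sig2, "GBM", "LGG")
  expect_gte(cmp$roc$sensitivity, 0.8)
  expect_gte(cmp$roc$specificity, 0.8)
  expect_true(all(c("GBM", "LGG") %in% cmp$histogram$true_label))
  # histogram percentages sum to 100 per label
  sums <- tapply(cmp$histogram$percent_samples, cmp$histogram$true_label, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
})

test_that("tumor/germline concordance: identical tables are clean", {
  set.seed(35)
  germ <- rbind(gt_rows("L1", "GBM", "12/14", 30L, prefix = "p"),
                gt_rows("L2", "GBM", "15/15", 30L, prefix = "p"))
  germ$genotype[sample(60L, 10L)] <- "14/14"
  tum <- germ
  conc <- tumor_germline_concordance(germ, tum, sig2)
  expect_equal(conc$concordance, c(1, 1))
  expect_equal(conc$p_value, c(1, 1))
  expect_false(any(conc$flagged))
  expect_equal(attr(conc, "overall_concordance"), 1)
})

test_that("a planted 50% genotype switch at one locus is flagged", {
  germ <- rbind(gt_rows("L1", "GBM", "14/14", 40L, prefix = "p"),
                gt_rows("L2", "GBM", "15/15", 40L, prefix = "p"))
  tum <- germ
  flip <- tum$locus_id == "L1" & as.integer(sub("p", "", tum$sample_id)) <= 20L
  tum$genotype[flip] <- "12/14"   # the L1 signature genotype
  conc <- tumor_germline_concordance(germ, tum, sig2)
  expect_true(conc$flagged[conc$locus_id == "L1"])
  expect_lt(conc$p_value[conc$locus_id == "L1"], 0.01)
  expect_false(conc$flagged[conc$locus_id == "L2"])
  expect_equal(conc$concordance[conc$locus_id == "L1"], 0.5)
  expect_error(tumor_germline_concordance(germ[0L, ], tum, sig2), "pairs")
})
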