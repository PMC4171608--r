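# association_stats: cohort filters, predominant genotype, Fisher exact,
# relative risk, and the BH signature cutoff

test_that("cohort filters drop under-called samples and sparse loci", {
  # 12 cases + 12 controls over 3 loci; one case sample called at only 1
  # locus (of 3); one locus called in just 9 controls
  tab <- gt_table(list(
    L1 = list(CASE = c("14/14" = 12L), CTRL = c("14/14" = 12L)),
    L2 = list(CASE = c("14/14" = 12L), CTRL = c("14/14" = 9L, "NA" = 3L)),
    L3 = list(CASE = c("14/14" = 12L), CTRL = c("14/14" = 12L))
  ))
  low <- tab$sample_id == "CASE001" & tab$locus_id != "L1"
  tab$status[low] <- "low_coverage"
  tab$genotype[low] <- NA_character_

  filt <- apply_cohort_filters(tab, min_loci_per_sample = 2L,
                               min_samples_per_locus = 10L)
  rep_ <- attr(filt, "filter_report")
  expect_equal(rep_$samples_dropped, "CASE001")
  expect_equal(rep_$loci_dropped, "L2")
  expect_false("CASE001" %in% filt$sample_id)
  expect_setequal(unique(filt$locus_id), c("L1", "L3"))

  # everything above threshold -> identity
  all_ok <- apply_cohort_filters(tab, min_loci_per_sample = 1L,
                                 min_samples_per_locus = 5L)
  expect_equal(nrow(all_ok), nrow(tab))
})

test_that("predominant genotype is the control mode with stated tie-breaks", {
  tab <- gt_table(list(
    L1 = list(CTRL = c("14/14" = 40L, "12/14" = 10L), CASE = c("12/14" = 5L))
  ))
  expect_equal(predominant_genotype(tab, "L1", "CTRL"), "14/14")

  tie <- gt_table(list(L1 = list(CTRL = c("14/14" = 25L, "12/12" = 25L))))
  expect_equal(predominant_genotype(tie, "L1", "CTRL", ref_length = 14L),
               "14/14")
  # no reference hint: numerically smallest pair
  expect_equal(predominant_genotype(tie, "L1", "CTRL"), "12/12")
  expect_error(predominant_genotype(tab, "L2", "CTRL"), "no called")
})

test_that("fisher_exact matches enumeration and fisher.test conventions", {
  expect_equal(fisher_exact(5L, 0L, 0L, 5L), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact(5L, 0L, 0L, 5L), 0.00793650794, tolerance = 1e-9)
  expect_equal(fisher_exact(10L, 10L, 10L, 10L), 1)
  # random spot checks against both oracles
  set.seed(21)
  for (i in 1:200) {
    a <- sample(0:25, 1L); b <- sample(0:25, 1L)
    c_ <- sample(0:25, 1L); d <- sample(0:25, 1L)
    if ((a + c_) == 0L || (b + d) == 0L) next
    p <- fisher_exact(a, b, c_, d)
    expect_equal(p, oracle_fisher(a, b, c_, d), tolerance = 1e-12)
    expect_equal(p,
                 stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_association builds the right 2x2 and relative risk", {
  tab <- gt_table(list(
    L1 = list(GBM = c("12/14" = 30L, "14/14" = 70L),
              NORM = c("12/14" = 10L, "14/14" = 90L))
  ))
  as1 <- fisher_association(tab, "L1", "12/14", "GBM", "NORM")
  expect_equal(c(as1$a, as1$b, as1$c, as1$d), c(30L, 70L, 10L, 90L))
  expect_equal(as1$relative_risk, 3)
  expect_equal(as1$p_value, fisher_exact(30L, 70L, 10L, 90L))

  # only callable samples enter the denominators
  tab2 <- rbind(tab, gt_rows("L1", "GBM", NA_character_, 5L,
                             status = "low_coverage", prefix = "GBMx"))
  as2 <- fisher_association(tab2, "L1", "12/14", "GBM", "NORM")
  expect_equal(as2$a + as2$b, 100L)

  # zero-carrier control: Inf sentinel plus Haldane companion
  tab3 <- gt_table(list(
    L1 = list(GBM = c("12/14" = 5L, "14/14" = 5L), NORM = c("14/14" = 10L))
  ))
  as3 <- fisher_association(tab3, "L1", "12/14", "GBM", "NORM")
  expect_equal(as3$relative_risk, Inf)
  expect_equal(as3$relative_risk_haldane,
               (5.5 / 11) / (0.5 / 11))
})

test_that("label swap inverts RR and preserves p", {
  set.seed(22)
  for (i in 1:20) {
    n1 <- sample(10:40, 1L); n2 <- sample(10:40, 1L)
    k1 <- sample(1:(n1 - 1L), 1L); k2 <- sample(1:(n2 - 1L), 1L)
    tab <- gt_table(list(
      L1 = list(A = c("12/14" = k1, "14/14" = n1 - k1),
                B = c("12/14" = k2, "14/14" = n2 - k2))
    ))
    ab <- fisher_association(tab, "L1", "12/14", "A", "B")
    ba <- fisher_association(tab, "L1", "12/14", "B", "A")
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_equal(ab$relative_risk, 1 / ba$relative_risk, tolerance = 1e-12)
  }
})

test_that("bh_reject reproduces the worked step-up example", {
  p <- c(0.0001, 0.002, 0.2, 0.9)
  # X = 4 hypotheses with p < 1 -> q* = 0.25; BH passes the first two
  X <- sum(p < 1)
  expect_equal(X, 4L)
  rej <- bh_reject(p, 1 / X)
  expect_equal(rej, c(TRUE, TRUE, FALSE, FALSE))
  assoc <- data.frame(locus_id = paste0("L", 1:4), genotype = "12/14",
                      a = 1L, b = 1L, c = 1L, d = 1L, p_value = p,
                      relative_risk = 1, relative_risk_haldane = 1,
                      predominant_control_genotype = "14/14")
  sig <- bh_signature_cutoff(assoc)
  expect_equal(sig$fdr_rule$X, 4L)
  expect_equal(sig$fdr_rule$q_star, 0.25)
  expect_equal(sig$caml_genotypes$locus_id, c("L1", "L2"))
  # all-ones p-vector: X = 0, empty signature
  assoc$p_value <- 1
  expect_equal(nrow(bh_signature_cutoff(assoc)$caml_genotypes), 0L)
})

test_that("BH step-up matches independent oracles on random p-vectors", {
  set.seed(23)
  for (i in 1:300) {
    m <- sample(1:150, 1L)
    p <- switch(sample(3L, 1L),
                stats::runif(m),
                round(stats::runif(m), 2L),               # heavy ties
                c(stats::rbeta(m, 0.2, 4), 1)[1:m])       # small p mass
    q <- sample(c(0.01, 0.05, 0.25, 1 / max(1L, sum(p < 1))), 1L)
    mine <- bh_reject(p, q)
    expect_equal(mine, oracle_bh(p, q))
    expect_equal(mine, stats::p.adjust(p, "BH") <= q)
  }
})

test_that("signature discovery recovers planted loci on a synthetic cohort", {
  cfg <- sim_config(seed = 5L, n_loci = 200L, n_case = 100L,
                    n_control = 100L, n_caml = 10L)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort_genotypes(cfg, ref$catalog)
  tab <- apply_cohort_filters(sim$genotypes, min_loci_per_sample = 150L,
                              min_samples_per_locus = 10L)
  assoc <- associate_cohorts(tab, "CASE", "CONTROL", catalog = ref$catalog)
  # every hypothesis is a non-predominant genotype at a surviving locus
  expect_true(all(assoc$genotype != assoc$predominant_control_genotype))
  sig <- bh_signature_cutoff(assoc)
  key <- function(d) paste(d$locus_id, d$genotype)
  planted <- key(sim$truth)
  got <- key(sig$caml_genotypes)
  expect_gte(sum(planted %in% got), 9L)             # >= 90% of 10
  expect_lte(sum(!got %in% planted), 1L)            # <= ~5% false members
  # members all satisfied both rules
  expect_true(all(sig$caml_genotypes$p_value <= 0.01))
})
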