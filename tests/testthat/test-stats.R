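# Variance-gated comparisons, significance classes, chi-square balance.

test_that("F-test: identical samples give F = 1, p = 1", {
  expect_equal(fTestVariance(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)
})

test_that("F-test: a 9-fold variance ratio at n = 10 is significant", {
  b <- c(0.3, 1.1, 2.4, 3.3, 4.9, 5.2, 6.8, 7.1, 8.5, 9.9)
  a <- b * 3                      # var(a) = 9 var(b) exactly
  p <- fTestVariance(a, b)
  expect_equal(p, 2 * pf(9, 9, 9, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(p, 0.05)
})

test_that("F-test limiting behaviour with zero variance", {
  expect_equal(fTestVariance(c(1, 1, 1), c(1, 2, 3)), 0)
  expect_equal(fTestVariance(c(2, 2), c(5, 5)), 1)
  expect_error(fTestVariance(1, c(1, 2)), class = "rq_insufficient_data")
})

test_that("F-test agrees with var.test on random fixtures", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    expect_equal(fTestVariance(a, b), var.test(a, b)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0, p = 1, n.s", {
  a <- c(2.2, 2.8, 3.1, 2.5)
  res <- varianceGatedTTest(a, a)
  expect_equal(res$t_stat, 0)
  expect_equal(res$t_p, 1)
  expect_equal(res$significance, "n.s")
})

test_that("equal-variance branch matches the textbook pooled t by hand", {
  a <- c(3.0, 3.2, 3.4, 3.6)
  b <- c(2.0, 2.2, 2.4, 2.6)
  res <- varianceGatedTTest(a, b)
  expect_equal(res$variance_assumption, "equal")
  # hand evaluation of the pooled formula
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(abs(t_hand), 6, lower.tail = FALSE)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$t_p, p_hand, tolerance = 1e-12)
  # independent route: stats::t.test
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$t_p, tt$p.value, tolerance = 1e-10)
})

test_that("unequal-variance branch matches the Welch formula", {
  set.seed(42)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 0, 5)
  res <- varianceGatedTTest(a, b)
  expect_equal(res$variance_assumption, "unequal")
  se <- sqrt(var(a) / 20 + var(b) / 20)
  df_w <- se^4 / ((var(a) / 20)^2 / 19 + (var(b) / 20)^2 / 19)
  t_hand <- (mean(a) - mean(b)) / se
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_w, tolerance = 1e-12)
  tt <- t.test(a, b)
  expect_equal(res$t_p, tt$p.value, tolerance = 1e-10)
})

test_that("the gate is consistent and Welch df never exceeds pooled df", {
  set.seed(13)
  for (i in 1:25) {
    a <- rnorm(sample(4:25, 1), sd = runif(1, 0.3, 4))
    b <- rnorm(sample(4:25, 1), sd = runif(1, 0.3, 4))
    res <- varianceGatedTTest(a, b)
    expect_identical(res$variance_assumption == "equal", res$f_p > 0.05)
    if (res$variance_assumption == "unequal")
      expect_lte(res$df, length(a) + length(b) - 2)
  }
})

test_that("swapping groups flips t and preserves p and percent difference", {
  set.seed(14)
  a <- rnorm(12, 3, 1); b <- rnorm(9, 2.4, 0.8)
  r1 <- varianceGatedTTest(a, b, "a", "b")
  r2 <- varianceGatedTTest(b, a, "b", "a")
  expect_equal(r1$t_stat, -r2$t_stat, tolerance = 1e-12)
  expect_equal(r1$t_p, r2$t_p, tolerance = 1e-12)
  expect_identical(r1$significance, r2$significance)
  expect_equal(r1$percent_difference, r2$percent_difference,
               tolerance = 1e-12)
})

test_that("significance classes follow the stated map", {
  expect_equal(classifySignificance(0.2), "n.s")
  expect_equal(classifySignificance(0.03), "*")
  expect_equal(classifySignificance(0.005), "**")
  expect_equal(classifySignificance(0.05), "n.s")  # > 0.05 rule; 0.05 is n.s
  expect_equal(classifySignificance(0.01), "*")
  expect_error(classifySignificance(1.2), class = "rq_validation_error")
  expect_error(classifySignificance(-0.1), class = "rq_validation_error")
})

test_that("percent differences reproduce the reported worked examples", {
  expect_equal(attr(percentDifference(3.15, 2.30), "rounded"), 37)
  expect_equal(attr(percentDifference(3.77, 2.73), "rounded"), 38)
  expect_equal(attr(percentDifference(2.68, 2.57), "rounded"), 4)
  expect_equal(as.numeric(percentDifference(2, 2)), 0)
  expect_error(percentDifference(3, 0), class = "rq_validation_error")
})

test_that("chi-square balance matches closed form and chisq.test", {
  r <- chiSquareBalance(50, 50)
  expect_equal(r$chi2_stat, 0)
  expect_equal(r$p, 1)
  r2 <- chiSquareBalance(58, 25)
  expect_equal(r2$chi2_stat, (58 - 41.5)^2 / 41.5 + (25 - 41.5)^2 / 41.5,
               tolerance = 1e-12)
  expect_equal(r2$chi2_stat, 13.12, tolerance = 0.005)
  expect_equal(r2$p, 2.9e-4, tolerance = 0.02)
  ct <- chisq.test(c(58, 25), correct = FALSE)
  expect_equal(r2$chi2_stat, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(r2$p, ct$p.value, tolerance = 1e-10)
  r3 <- chiSquareBalance(1, 0)
  expect_equal(r3$chi2_stat, 1)
  expect_equal(r3$p, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(chiSquareBalance(0, 0), class = "rq_insufficient_data")
})

makeAnalysis <- function(n, region = "lateral", orientation = "ML",
                         sex = "F", irv = 3, somites = 7,
                         embryo = sprintf("E%03d", seq_len(n))) {
  data.frame(recording_id = paste0("R", seq_len(n), region, orientation, sex),
             embryo_id = embryo, irv = irv, region = region,
             orientation = orientation, sex = sex, somites = somites,
             stringsAsFactors = FALSE)
}

test_that("a degenerate group yields insufficient-data without failing others", {
  set.seed(15)
  analysis <- rbind(
    makeAnalysis(10, "lateral", "ML", "F", rnorm(10, 3.2, 0.5)),
    makeAnalysis(10, "midline", "ML", "F", rnorm(10, 2.3, 0.5),
                 embryo = sprintf("E1%02d", 1:10)),
    makeAnalysis(1, "lateral", "ML", "M", 2.8, embryo = "E900"))
  res <- cohortComparisons(analysis)
  cmp <- res$comparisons
  maleRows <- grepl("sex:M", cmp$group_a)
  expect_true(all(cmp$status[maleRows] == "insufficient-data"))
  femaleRegion <- cmp[grepl("sex:F", cmp$group_a) & cmp$comparison == "region", ]
  expect_equal(femaleRegion$status, "ok")
  expect_equal(res$sexBalance$n_female, 20)
  expect_equal(res$sexBalance$n_male, 1)
})

test_that("comparison rows satisfy their internal invariants", {
  set.seed(16)
  analysis <- rbind(
    makeAnalysis(12, "lateral", "ML", "F", rnorm(12, 3.8, 0.6)),
    makeAnalysis(12, "lateral", "RC", "F", rnorm(12, 2.7, 0.6),
                 embryo = sprintf("E2%02d", 1:12)),
    makeAnalysis(12, "midline", "ML", "F", rnorm(12, 2.3, 0.6),
                 embryo = sprintf("E3%02d", 1:12)),
    makeAnalysis(12, "midline", "RC", "F", rnorm(12, 2.3, 0.6),
                 embryo = sprintf("E4%02d", 1:12)))
  cmp <- cohortComparisons(analysis)$comparisons
  okRows <- cmp[cmp$status == "ok", ]
  expect_identical(okRows$variance_assumption == "equal", okRows$f_p > 0.05)
  for (i in seq_len(nrow(okRows))) {
    lo <- min(okRows$mean_a[i], okRows$mean_b[i])
    hi <- max(okRows$mean_a[i], okRows$mean_b[i])
    expect_equal(okRows$percent_difference[i], (hi - lo) / lo * 100,
                 tolerance = 1e-9)
    expect_identical(okRows$significance[i],
                     classifySignificance(okRows$t_p[i]))
  }
})

test_that("the region difference reported for females is detectable", {
  # cohorts generated at the reported female means (lateral 3.15 vs midline
  # 2.30): the lateral-vs-midline comparison should reach significance in
  # at least 80% of replicates
  gm <- defaultGroupMeans()
  gm$v0 <- ifelse(gm$region == "lateral", 3.15, 2.30)
  hits <- vapply(1:50, function(i) {
    cfg <- simulationConfig(groupMeans = gm, embryoSd = 0.4, withinSd = 0.6,
                            nEmbryos = 25, ablationsPerEmbryo = 2,
                            femaleProb = 1, seed = 500 + i)
    sim <- simulateCohort(cfg)
    mm <- measureCohort(sim$recordings, blinded = FALSE)
    qc <- applyExclusions(mm, sim$metadata)
    cmp <- cohortComparisons(qc$analysis)$comparisons
    row <- cmp[cmp$comparison == "region" & grepl("sex:F", cmp$group_a), ]
    isTRUE(row$t_p < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
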