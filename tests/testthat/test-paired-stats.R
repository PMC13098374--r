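test_that("normality gate routes by Shapiro-Wilk and handles degeneracy", {
  ## two-point mass is far from normal
  bimodal <- rep(c(0, 10), 10) + seq(0, 0.19, by = 0.01)
  expect_identical(normalityGate(bimodal)$route, "nonparametric")
  ## exact normal quantiles pass
  normish <- qnorm((1:20 - 0.5) / 20)
  gate <- normalityGate(normish)
  expect_identical(gate$route, "parametric")
  expect_equal(gate$normality_p, shapiro.test(normish)$p.value,
               tolerance = 1e-3)
  const <- normalityGate(rep(3, 10))
  expect_identical(const$route, "nonparametric")
  expect_equal(const$normality_p, 0)
  expect_error(normalityGate(c(1, 2)), "at least 3")
})

test_that("mean-difference CI matches the closed form and t.test", {
  ci <- meanDifferenceCI(c(1, 2, 3))
  expect_equal(ci$mean, 2)
  expect_equal(ci$ci_low, 2 - qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
  expect_equal(ci$ci_high, 2 + qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
  expect_equal(round(c(ci$ci_low, ci$ci_high), 3), c(-0.484, 4.484))
  set.seed(7)
  for (i in 1:5) {
    d <- rnorm(8 + i)
    ci <- meanDifferenceCI(d)
    tt <- t.test(d)
    expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-10)
  }
  cc <- meanDifferenceCI(rep(4.2, 5))
  expect_equal(c(cc$mean, cc$ci_low, cc$ci_high), c(4.2, 4.2, 4.2))
  ## antisymmetry under sign flip
  a <- meanDifferenceCI(c(1, 2, 3)); b <- meanDifferenceCI(-c(1, 2, 3))
  expect_equal(c(b$mean, b$ci_low, b$ci_high),
               -c(a$mean, a$ci_high, a$ci_low), tolerance = 1e-12)
})

test_that("paired t branch matches the closed-form t statistic", {
  res <- pairedTest(c(2, 3, 4), c(1, 1, 1), force = "parametric")
  expect_identical(res$test_used, "paired_t")
  expect_equal(res$mean_difference, 2)
  expect_equal(res$p_value, 2 * pt(-abs(2 / (1 / sqrt(3))), df = 2),
               tolerance = 1e-10)
  expect_equal(round(res$p_value, 4), 0.0742)
  expect_equal(round(c(res$ci_low, res$ci_high), 3), c(-0.484, 4.484))
})

test_that("Wilcoxon branch is exact and matches sign enumeration", {
  res <- pairedTest(c(2, 3, 4), c(1, 1, 1), force = "nonparametric")
  expect_identical(res$test_used, "wilcoxon")
  expect_equal(res$p_value, 0.25)  # 2/2^3 sign assignments as extreme
  ## random differences with ties and zeros, n <= 10: DP == enumeration
  set.seed(11)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    d <- sample(c(-3:3), n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
    if (all(d == 0)) d[1] <- 1
    expect_equal(wilcoxonSignedRank(d)$p_value, enumSignedRankP(d),
                 tolerance = 1e-12, info = paste("case", i))
  }
  ## against stats::wilcox.test where it is exact (no ties, no zeros)
  set.seed(12)
  for (i in 1:5) {
    d <- rnorm(9)
    expect_equal(wilcoxonSignedRank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  ## large-sample normal approximation stays close to the exact p
  set.seed(13)
  d <- rnorm(30, mean = 0.3)
  pApprox <- wilcoxonSignedRank(d)$p_value
  pExact <- wilcoxonSignedRank(d, exactMax = 30)$p_value
  expect_equal(pApprox, pExact, tolerance = 0.02)
})

test_that("identical pre and post give zero difference and p = 1", {
  res <- pairedTest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p_value, 1)
})

test_that("swapping pre and post negates the difference, not the p-value", {
  set.seed(21)
  pre <- rnorm(15, 10); post <- rnorm(15, 9)
  a <- pairedTest(pre, post)
  b <- pairedTest(post, pre)
  expect_equal(b$mean_difference, -a$mean_difference, tolerance = 1e-12)
  expect_equal(c(b$ci_low, b$ci_high), -c(a$ci_high, a$ci_low),
               tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
})

test_that("variable summaries follow the mean/SD and median/IQR rules", {
  p <- summarizeVariable(1:4, "parametric")
  expect_equal(p$center, 2.5)
  expect_equal(p$sd, sd(1:4), tolerance = 1e-12)
  expect_equal(round(p$sd, 2), 1.29)
  np <- summarizeVariable(1:4, "nonparametric")
  expect_equal(np$center, 2.5)
  expect_equal(c(np$spread_low, np$spread_high), c(1.75, 3.25))
  one <- summarizeVariable(5, "parametric")
  expect_true(one$degenerate)
  expect_equal(one$sd, 0)
  expect_error(summarizeVariable(numeric(0)), "no values")
})

test_that("summary differences reproduce published worked examples", {
  expect_equal(summaryDifference(4.21, 3.69), 0.52)
  expect_equal(summaryDifference(1.04, 0.73), 0.31)
  expect_equal(summaryDifference(2, 2), 0)
})

test_that("comparison table handles phases, drops incomplete pairs, flags effects", {
  set.seed(31)
  n <- 12
  long <- rbind(
    pairedLong(rnorm(n, 10), rnorm(n, 10), "TTDi", phase = "ES"),
    pairedLong(rnorm(n, 11, 0.5), rnorm(n, 10, 0.5), "APDi", phase = "ES"),
    pairedLong(rnorm(n, 4.2, 0.3), rnorm(n, 4.2, 0.3), "LVEDVi"))
  ## remove one post measurement -> that subject dropped for APDi only
  drop <- long$variable == "APDi" & long$visit == "post" &
    long$subject_id == "S01"
  expect_message(tbl <- comparisonTable(long[!drop, ]), "dropped 1")
  expect_equal(nrow(tbl), 3)
  apd <- tbl[tbl$variable == "APDi", ]
  expect_equal(apd$n, n - 1)
  expect_true(apd$significant)
  expect_false(tbl$significant[tbl$variable == "TTDi"])
  ## empty variable selection gives an empty table
  expect_equal(nrow(comparisonTable(long, variables = character(0))), 0)
  fmt <- formatComparisonTable(tbl)
  expect_identical(names(fmt)[1:4], c("Variable", "Phase", "Pre", "Post"))
  expect_identical(fmt$Flag[tbl$variable == "APDi"], "*")
})
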