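test_that("group summaries match the direct formulas", {
  s1 <- summarize_group(5)
  expect_identical(s1$n, 1L)
  expect_identical(s1$mean, 5)
  expect_true(is.na(s1$sd) && is.na(s1$sem))
  s2 <- summarize_group(c(1, 3))
  expect_equal(s2$sd, sqrt(2))
  expect_equal(s2$sem, 1)
  set.seed(22)
  v <- rnorm(23)
  s3 <- summarize_group(v)
  expect_equal(s3$mean, sum(v) / 23, tolerance = 1e-12)
  expect_equal(s3$sd, sqrt(sum((v - mean(v))^2) / 22), tolerance = 1e-12)
  expect_error(summarize_group(numeric(0)), "empty")
})

test_that("Mann-Whitney matches forced examples and full enumeration", {
  tied <- mann_whitney_u(1, 1)
  expect_equal(tied$statistic, 0.5)           # n1*n2/2 under midranks
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)              # 2 * (1/20), exact
  ## enumeration oracle across random small untied samples
  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(seq(1, 400), n1) / 7
    b <- (sample(seq(401, 800), n2) + 0.5) / 7 - 20   # offset: no cross-ties
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
  }
  ## p decreases as the separation between disjoint samples grows is
  ## reflected in the monotone rank statistic reaching its extreme
  p_far <- mann_whitney_u(c(1, 2, 3, 4), c(10, 11, 12, 13))$p_value
  p_mixed <- mann_whitney_u(c(1, 2, 3, 10), c(4, 11, 12, 13))$p_value
  expect_lte(p_far, p_mixed)
})

test_that("Mann-Whitney is invariant under monotone transforms", {
  set.seed(24)
  a <- runif(7, 1, 2); b <- runif(9, 1.2, 2.4)
  p0 <- mann_whitney_u(a, b)$p_value
  expect_equal(mann_whitney_u(exp(a), exp(b))$p_value, p0, tolerance = 1e-12)
  expect_equal(mann_whitney_u(log(a), log(b))$p_value, p0, tolerance = 1e-12)
})

test_that("Welch's t matches the textbook formula", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  eps <- 1e-6
  tiny <- welch_t(c(0, eps), c(1, 1 + eps))
  expect_gt(abs(tiny$statistic), 1e4)
  expect_lt(tiny$p_value, 1e-4)
  set.seed(25)
  a <- rnorm(9, 1, 2); b <- rnorm(14, 0, 0.5)
  got <- welch_t(a, b)
  se2 <- var(a) / 9 + var(b) / 14
  t_oracle <- (mean(a) - mean(b)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(a) / 9)^2 / 8 + (var(b) / 14)^2 / 13)
  expect_equal(got$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(got$df, df_oracle, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(t_oracle), df_oracle), tolerance = 1e-10)
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("Wilcoxon signed-rank matches forced examples and enumeration", {
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  dec <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(4, 3.5, 6.5, 6.2, 8.9))
  expect_equal(dec$statistic, 0)              # all differences negative
  expect_equal(dec$p_value, 0.0625)           # 2 / 2^5, exact
  set.seed(26)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    before <- sample(seq(1, 500), n) / 3
    after <- before + sample(c(-1, 1), n, TRUE) * sample(seq(1, 99), n) / 100
    got <- wilcoxon_signed_rank(before, after)$p_value
    expect_equal(got, oracle_wsr_p(after - before), tolerance = 1e-12)
    ## sign-flip symmetry
    expect_equal(wilcoxon_signed_rank(after, before)$p_value, got, tolerance = 1e-12)
  }
})

test_that("the Shapiro-Wilk gate separates normal from bimodal samples", {
  expect_false(shapiro_wilk_gate(c(1, 2)))     # guard: too small
  set.seed(27)
  gauss_pass <- mean(vapply(1:200, function(i)
    shapiro_wilk_gate(rnorm(30)), logical(1)))
  expect_gt(gauss_pass, 0.9)                   # type-I rate near 0.05
  bimodal <- c(rnorm(25, -5, 0.3), rnorm(25, 5, 0.3))
  expect_false(shapiro_wilk_gate(bimodal))
})

test_that("compare_groups follows the documented gate policy", {
  set.seed(28)
  a <- rnorm(12); b <- rnorm(13, 1)
  res <- compare_groups(a, b)
  expect_true(res$normal)
  expect_identical(res$chosen$test_name, "welch_t")
  heavy <- c(rnorm(12), 40, 80)
  res2 <- compare_groups(heavy, b)
  expect_false(res2$normal)
  expect_identical(res2$chosen$test_name, "mann_whitney_u")
  ## both branches are always computed and stored
  expect_s3_class(res2$parametric, "test_result")
  expect_s3_class(res2$nonparametric, "test_result")
  pr <- compare_groups(a, a + rnorm(12, 0.5), paired = TRUE)
  expect_true(pr$chosen$test_name %in% c("paired_t", "wilcoxon_signed_rank"))
})
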