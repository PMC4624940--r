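test_that("ICC(2,1) matches hand and ANOVA computations", {
  # perfect agreement
  expect_equal(icc_2_1(1:10, 1:10)$icc, 1)

  # constant offset on a 4-subject table: hand mean squares give 10/85,
  # and absolute agreement drops below the Pearson r of 1
  ic <- icc_2_1(1:4, 1:4 + 5)
  expect_equal(ic$icc, 10 / 85, tolerance = 1e-12)
  expect_lt(ic$icc, pearson_ci(1:4, 1:4 + 5)$r)

  # frozen external-reference dataset (two-way random, absolute agreement)
  x <- c(21.46, 37.58, 24.78, 28.44, 29.55, 25.55, 21.79, 33.89, 32.17,
         18.28, 44.08, 35.81)
  y <- c(21.06, 41.34, 25.11, 29.79, 33.02, 23.91, 24.73, 38.89, 36.98,
         19.03, 47.84, 33.26)
  ic2 <- icc_2_1(x, y)
  expect_equal(ic2$icc, 0.934625249529, tolerance = 1e-10)
  expect_equal(round(ic2$icc_lo, 2), 0.71)
  expect_equal(round(ic2$icc_hi, 2), 0.98)

  # agreement with a direct aov decomposition on random 4x2..12x2 tables
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- rnorm(n, 20, 4)
    b <- a + rnorm(n, 0.5, 1.5)
    expect_equal(icc_2_1(a, b)$icc, aov_icc_2_1(a, b), tolerance = 1e-10)
  }

  # negative estimates are allowed; degenerate input errors
  set.seed(1)
  xa <- rnorm(8); ya <- -xa + rnorm(8, 0, 0.1)
  expect_lt(icc_2_1(xa, ya)$icc, 0)
  expect_error(icc_2_1(rep(2, 5), rep(2, 5)), class = "rfdtools_degenerate")
  expect_error(icc_2_1(1:2, 2:3), class = "rfdtools_too_few_pairs")

  # parameter recovery: variance components 9/1 -> ICC 0.9 within 0.01
  set.seed(101)
  subj <- rnorm(2000, 0, 3)
  est <- icc_2_1(30 + subj + rnorm(2000), 30 + subj + rnorm(2000))$icc
  expect_equal(est, 0.9, tolerance = 0.011)
})

test_that("SEM and MDC follow the reliability formulas in both variants", {
  expect_equal(sem_abs(4.92, 1), 0)
  expect_equal(sem_abs(10, 0.75), 5)
  expect_gt(sem_abs(1, -0.5), 1) # negative ICC inflates the SEM

  # worked example: SD1 4.92, ICC ~0.89, mean 19.19 -> SEM% about 8.5
  expect_equal(sem_pct(4.92, 0.89, 19.19), 8.503, tolerance = 1e-3)

  expect_equal(mdc(8.62, "sqrt2"), 23.89, tolerance = 0.01)
  expect_equal(mdc(6.92, "plain"), 13.56, tolerance = 0.01)
  expect_equal(mdc(0, "sqrt2"), 0)
  expect_equal(mdc(0, "plain"), 0)
  # the MDC/SEM ratio is exact per variant on any input
  for (s in c(0.001, 0.5, 7.3, 120)) {
    expect_equal(mdc(s, "sqrt2") / s, 1.96 * sqrt(2))
    expect_equal(mdc(s, "plain") / s, 1.96)
  }
  expect_error(sem_pct(1, 0.5, 0), class = "rfdtools_degenerate")
})

test_that("Pearson and concordance coefficients match moment arithmetic", {
  expect_equal(pearson_ci(1:10, 2 * (1:10) + 3)$r, 1)
  expect_equal(pearson_ci(1:10, -(1:10))$r, -1)
  # direct hand computation: cov 1, variances 5/3 -> r = 0.6
  expect_equal(pearson_ci(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson_ci(1:5, rep(2, 5)), class = "rfdtools_degenerate")

  # Fisher-z interval agrees with cor.test (same transform)
  set.seed(3)
  a <- rnorm(30); b <- a + rnorm(30)
  ours <- pearson_ci(a, b)
  ct <- stats::cor.test(a, b)
  expect_equal(ours$r_lo, ct$conf.int[1], tolerance = 1e-4)
  expect_equal(ours$r_hi, ct$conf.int[2], tolerance = 1e-4)

  # concordance: identity line, offset limit, closed-form moments
  expect_equal(lin_ccc(1:10, 1:10)$rc, 1)
  expect_lt(lin_ccc(1:10, 1:10 + 1000)$rc, 0.001)
  xs <- c(1, 2, 3, 4); ys <- c(2, 4, 6, 8)
  mo <- function(v) mean((v - mean(v))^2)
  rc_hand <- 2 * mean((xs - mean(xs)) * (ys - mean(ys))) /
    (mo(xs) + mo(ys) + (mean(xs) - mean(ys))^2)
  expect_equal(lin_ccc(xs, ys)$rc, rc_hand)

  # frozen Lin-1989 CI reference values
  x <- c(21.46, 37.58, 24.78, 28.44, 29.55, 25.55, 21.79, 33.89, 32.17,
         18.28, 44.08, 35.81)
  y <- c(21.06, 41.34, 25.11, 29.79, 33.02, 23.91, 24.73, 38.89, 36.98,
         19.03, 47.84, 33.26)
  cc <- lin_ccc(x, y)
  expect_equal(cc$rc, 0.929103439934, tolerance = 1e-10)
  expect_equal(cc$rc_lo, 0.807003406336, tolerance = 1e-8)
  expect_equal(cc$rc_hi, 0.975024107040, tolerance = 1e-8)

  # |rc| <= |r| on random samples; equality iff no location/scale shift
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(20, 10, 2); b <- 0.8 * a + rnorm(20, 3, 1)
    expect_lte(abs(lin_ccc(a, b)$rc), abs(pearson_ci(a, b)$r) + 1e-12)
  }
  expect_error(lin_ccc(rep(1, 5), rep(1, 5)), class = "rfdtools_degenerate")
})

test_that("Bland-Altman selects the right kind and limits", {
  # identical measurements: zero bias, zero-width limits, standard kind
  ba0 <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ba0$kind, "standard")
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  # Monte-Carlo: constant offset 2 with unit noise
  set.seed(21)
  x <- rnorm(10000, 30, 5)
  y <- x - 2 + rnorm(10000, 0, 1)
  ba <- bland_altman(x, y)
  expect_equal(ba$kind, "standard")
  expect_equal(ba$bias, 2, tolerance = 3 / sqrt(10000) / 2)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96, tolerance = 0.05)

  # strong difference-vs-average correlation triggers the regression kind
  set.seed(22)
  a <- rnorm(200, 30, 5)
  d <- 0.5 * a + rnorm(200, 0, 1) # corr(d, a) ~ 0.9
  xr <- a + d / 2; yr <- a - d / 2
  bar <- bland_altman(xr, yr)
  expect_equal(bar$kind, "regression_based")
  expect_gt(abs(bar$proportional_bias_r), 0.5)
  # the bias line recovers d ~ 0.5 * a
  expect_equal(bar$bias_line[2], 0.5, tolerance = 0.1)
  expect_gt(bar$loa_high_line[1] - bar$bias_line[1], 0)
})

test_that("coefficient bands partition [-1, 1] and match printed conventions", {
  expect_equal(as.character(classify_coefficient(0.90)), "excellent")
  expect_equal(as.character(classify_coefficient(0.75)), "good")
  expect_equal(as.character(classify_coefficient(0.7449)), "moderate")
  expect_equal(as.character(classify_coefficient(0.749)), "good") # rounds to 0.75
  expect_equal(as.character(classify_coefficient(-0.93)), "poor")
  vals <- seq(-1, 1, by = 0.005)
  bands <- classify_coefficient(vals)
  expect_true(all(!is.na(bands)))
  expect_equal(levels(bands), c("poor", "moderate", "good", "excellent"))
  expect_error(classify_coefficient(1.2), class = "rfdtools_invalid_spec")
})

test_that("method-column summaries reproduce median/IQR/count conventions", {
  s200 <- summarize_method_column(c(0.77, 0.95, 0.88, 0.92, 0.87, 0.94,
                                    0.98, 0.93))
  expect_equal(s200$median, 0.93) # 0.925 rounds half away from zero
  expect_equal(s200$n_below_threshold, 0)

  ttp <- summarize_method_column(c(-0.93, 0.67, -0.47, 0.46, 0.40, 0.70,
                                   0.75, 0.39))
  expect_equal(ttp$median, 0.43)
  expect_equal(ttp$n_below_threshold, 7) # 0.75 itself is not below
  expect_equal(ttp$iqr_25, 0.18)
  expect_equal(ttp$iqr_75, 0.68)

  const <- summarize_method_column(rep(0.8, 8))
  expect_equal(const$median, 0.80)
  expect_equal(const$iqr_25, 0.80)
  expect_equal(const$iqr_75, 0.80)
  expect_equal(const$n_below_threshold, 0)
  expect_error(summarize_method_column(0.9), class = "rfdtools_too_few_pairs")
})

test_that("Fisher-z intervals achieve nominal coverage on bivariate normals", {
  # 400 simulations at n = 50, true r = 0.6
  set.seed(31)
  rho <- 0.6
  hits <- 0
  for (i in 1:400) {
    a <- rnorm(50)
    b <- rho * a + sqrt(1 - rho^2) * rnorm(50)
    ci <- pearson_ci(a, b)
    hits <- hits + (ci$r_lo <= rho && rho <= ci$r_hi)
  }
  expect_gte(hits / 400, 0.93)
  expect_lte(hits / 400, 0.97)
})
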