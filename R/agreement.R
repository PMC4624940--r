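#' Complete paired sample
#'
#' Drops pairs with a missing member (pairwise complete-case) and returns
#' the pairs entering an agreement analysis.
#'
#' @param x,y Numeric vectors of equal length: the two measurements per
#'   subject (e.g. session 1 vs session 2).
#' @param subject Optional subject identifiers.
#' @param label Comparison label carried into results.
#' @return A tibble with columns `subject`, `x`, `y` and attribute `label`.
#' @export
paired_sample <- function(x, y, subject = seq_along(x), label = NULL) {
  if (length(x) != length(y)) {
    abort_rfd("x and y must have equal length", "rfdtools_invalid_pairs")
  }
  ok <- is.finite(x) & is.finite(y)
  out <- tibble::tibble(subject = as.character(subject[ok]),
                        x = as.double(x[ok]), y = as.double(y[ok]))
  attr(out, "label") <- label
  out
}

check_pairs <- function(x, y, min_n = 3) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) {
    abort_rfd(sprintf("need at least %d complete pairs (have %d)",
                      min_n, sum(ok)), "rfdtools_too_few_pairs")
  }
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Two-way random-effects, absolute-agreement, single-measures ICC
#'
#' The ICC(2,1) of Shrout and Fleiss: both subjects and
#' measurement occasions are treated as random samples and systematic
#' offsets between occasions count against agreement. Computed from the
#' two-way ANOVA mean squares as
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`
#' occasions; the estimate can be negative. The 95% confidence interval
#' uses the F-distribution method with Satterthwaite degrees of freedom.
#'
#' @param x,y The two measurements per subject (k = 2 columns).
#' @param conf Confidence level, default 0.95.
#' @return One-row tibble: `icc`, `icc_lo`, `icc_hi`, `n`, and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(x, y, conf = 0.95) {
  p <- check_pairs(x, y)
  m <- cbind(p$x, p$y)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    abort_rfd("zero total variance: ICC undefined", "rfdtools_degenerate")
  }
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))

  alpha <- 1 - conf
  # F-based interval (Shrout-Fleiss / McGraw-Wong), Satterthwaite df
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  tibble::tibble(icc = icc, icc_lo = lo, icc_hi = hi, n = n,
                 msr = msr, msc = msc, mse = mse)
}

#' Standard error of measurement and minimal detectable change
#'
#' `sem_abs()` multiplies the standard deviation of the first-session
#' values by the square root of one minus the ICC: `SEM = SD1 * sqrt(1 -
#' ICC)` (a negative ICC gives a factor above 1, as it should).
#' `mdc()` converts a SEM to the minimal detectable change at 95%
#' confidence. Two multiplier conventions circulate in the clinimetric
#' literature and both appear in published reliability tables, so both are
#' first-class: `"sqrt2"` gives `1.96 * sqrt(2) * SEM` (ratio 2.7719) and
#' `"plain"` gives `1.96 * SEM`. Percent versions divide by a reference
#' mean (the first-session mean by convention).
#'
#' @param sd1 Standard deviation of the first-session values (>= 0).
#' @param icc ICC estimate in `[-1, 1]`.
#' @return `sem_abs`: SEM in the data's units.
#' @export
sem_abs <- function(sd1, icc) {
  if (any(sd1 < 0)) abort_rfd("sd1 must be >= 0", "rfdtools_invalid_spec")
  if (any(icc > 1)) abort_rfd("icc cannot exceed 1", "rfdtools_invalid_spec")
  sd1 * sqrt(1 - icc)
}

#' @rdname sem_abs
#' @param mean_ref Reference mean for percentaging; must be nonzero.
#' @export
sem_pct <- function(sd1, icc, mean_ref) {
  if (any(mean_ref == 0)) {
    abort_rfd("percent SEM undefined for zero reference mean",
              "rfdtools_degenerate")
  }
  100 * sem_abs(sd1, icc) / mean_ref
}

#' @rdname sem_abs
#' @param sem A SEM (absolute or percent; the multiplier is unit-free).
#' @param variant `"sqrt2"` (default) or `"plain"`.
#' @param z Normal quantile, default 1.96.
#' @export
mdc <- function(sem, variant = c("sqrt2", "plain"), z = 1.96) {
  variant <- match.arg(variant)
  if (any(sem < 0)) abort_rfd("sem must be >= 0", "rfdtools_invalid_spec")
  mult <- switch(variant, sqrt2 = z * sqrt(2), plain = z)
  mult * sem
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Paired measurements (n >= 3, both with nonzero variance).
#' @param conf Confidence level, default 0.95.
#' @param z Normal quantile used for the interval, default 1.96.
#' @return One-row tibble: `r`, `r_lo`, `r_hi`, `n`.
#' @export
pearson_ci <- function(x, y, conf = 0.95, z = 1.96) {
  p <- check_pairs(x, y)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) {
    abort_rfd("zero variance: correlation undefined", "rfdtools_degenerate")
  }
  r <- stats::cor(p$x, p$y)
  if (p$n > 3 && abs(r) < 1) {
    zr <- atanh(r)
    se <- 1 / sqrt(p$n - 3)
    lo <- tanh(zr - z * se); hi <- tanh(zr + z * se)
  } else {
    lo <- NA_real_; hi <- NA_real_
  }
  tibble::tibble(r = r, r_lo = lo, r_hi = hi, n = p$n)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the line of identity `y = x`: the Pearson correlation
#' penalised for location and scale shift,
#' `rc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with biased
#' (1/n) moments. The confidence interval uses Lin's (1989) asymptotic
#' variance of the Fisher z-transform of `rc`.
#'
#' @inheritParams pearson_ci
#' @return One-row tibble: `rc`, `rc_lo`, `rc_hi`, `n`.
#' @export
lin_ccc <- function(x, y, conf = 0.95, z = 1.96) {
  p <- check_pairs(x, y)
  n <- p$n
  mx <- mean(p$x); my <- mean(p$y)
  sx2 <- mean((p$x - mx)^2); sy2 <- mean((p$y - my)^2)
  sxy <- mean((p$x - mx) * (p$y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    abort_rfd("zero variances and zero mean gap: concordance undefined",
              "rfdtools_degenerate")
  }
  rc <- 2 * sxy / denom
  lo <- NA_real_; hi <- NA_real_
  if (sx2 > 0 && sy2 > 0 && n > 2) {
    r <- sxy / sqrt(sx2 * sy2)
    if (abs(r) > 0 && abs(rc) < 1) {
      u <- (mx - my) / (sx2 * sy2)^0.25
      se_z2 <- ((1 - r^2) * rc^2 / ((1 - rc^2) * r^2) +
                  2 * rc^3 * (1 - rc) * u^2 / (r * (1 - rc^2)^2) -
                  rc^4 * u^4 / (2 * r^2 * (1 - rc^2)^2)) / (n - 2)
      if (is.finite(se_z2) && se_z2 >= 0) {
        se <- sqrt(se_z2)
        lo <- tanh(atanh(rc) - z * se)
        hi <- tanh(atanh(rc) + z * se)
      }
    }
  }
  tibble::tibble(rc = rc, rc_lo = lo, rc_hi = hi, n = n)
}

#' Bland-Altman limits of agreement
#'
#' Computes per-subject differences `d = x - y` and averages
#' `a = (x + y) / 2`. If the correlation between differences and averages
#' does not exceed the proportional-bias threshold (|r| <= 0.50), the
#' standard analysis applies: bias = mean difference, limits of agreement
#' = bias +/- 1.96 SD(d). Otherwise the regression-based variant of Bland
#' and Altman (1999) is used: the bias is a regression line of `d` on
#' `a`, and the limits are that line +/- 1.96 sqrt(pi/2) times the fitted
#' regression of |residuals| on `a`.
#'
#' @inheritParams pearson_ci
#' @param prop_threshold Proportional-bias trigger on |cor(d, a)|,
#'   default 0.50.
#' @return A `bland_altman` object: list with `kind`, `n`,
#'   `proportional_bias_r`, and either scalars `bias`, `loa_low`,
#'   `loa_high` (standard) or coefficient pairs `bias_line`,
#'   `loa_low_line`, `loa_high_line` as `(intercept, slope)`
#'   (regression-based), plus the `data` tibble.
#' @export
bland_altman <- function(x, y, prop_threshold = 0.5) {
  p <- check_pairs(x, y)
  d <- p$x - p$y
  a <- (p$x + p$y) / 2
  prop_r <- if (stats::sd(d) > 0 && stats::sd(a) > 0) stats::cor(d, a) else 0
  dat <- tibble::tibble(average = a, difference = d)
  if (abs(prop_r) <= prop_threshold) {
    bias <- mean(d)
    s <- stats::sd(d)
    out <- list(kind = "standard", n = p$n, proportional_bias_r = prop_r,
                bias = bias, loa_low = bias - 1.96 * s,
                loa_high = bias + 1.96 * s, sd_diff = s, data = dat)
  } else {
    fit_bias <- stats::lm(d ~ a)
    res <- stats::residuals(fit_bias)
    fit_spread <- stats::lm(abs(res) ~ a)
    half_width <- 1.96 * sqrt(pi / 2) * stats::coef(fit_spread)
    bias_line <- stats::coef(fit_bias)
    out <- list(kind = "regression_based", n = p$n,
                proportional_bias_r = prop_r,
                bias_line = unname(bias_line),
                loa_low_line = unname(bias_line - half_width),
                loa_high_line = unname(bias_line + half_width),
                data = dat)
  }
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  if (x$kind == "standard") {
    cat(sprintf("<bland_altman standard> n=%d bias=%.3f LoA=[%.3f, %.3f] prop-bias r=%.2f\n",
                x$n, x$bias, x$loa_low, x$loa_high, x$proportional_bias_r))
  } else {
    cat(sprintf("<bland_altman regression-based> n=%d bias=%.3f%+.3f*a prop-bias r=%.2f\n",
                x$n, x$bias_line[1], x$bias_line[2], x$proportional_bias_r))
  }
  invisible(x)
}

#' Interpretation band for a reliability or correlation coefficient
#'
#' Maps a coefficient to the conventional clinimetric interpretation:
#' excellent (>= 0.90), good (0.75-0.89), moderate (0.50-0.74), poor
#' (< 0.50). The value is first rounded half away from zero to two
#' decimals so that a printed 0.75 classifies as good.
#'
#' @param value Coefficient(s) in `[-1, 1]`.
#' @return Factor with levels poor < moderate < good < excellent.
#' @export
classify_coefficient <- function(value) {
  if (any(value < -1 | value > 1, na.rm = TRUE)) {
    abort_rfd("coefficients must lie in [-1, 1]", "rfdtools_invalid_spec")
  }
  v <- round_half_away(value, 2)
  band <- dplyr::case_when(
    v >= 0.90 ~ "excellent",
    v >= 0.75 ~ "good",
    v >= 0.50 ~ "moderate",
    TRUE ~ "poor"
  )
  factor(band, levels = c("poor", "moderate", "good", "excellent"),
         ordered = TRUE)
}

#' Summarise one RFD method's per-muscle ICC column
#'
#' The method-comparison summary: median, interquartile range (25th/75th
#' percentiles, linear interpolation / quantile type 7) and the count of
#' muscle groups whose ICC falls below the good-reliability threshold.
#' Reported values are rounded to two decimals, half away from zero.
#'
#' @param iccs Numeric vector of per-muscle ICCs (>= 2 values).
#' @param threshold Reliability threshold, default 0.75.
#' @return One-row tibble: `median`, `iqr_25`, `iqr_75`,
#'   `n_below_threshold`, `n`.
#' @export
summarize_method_column <- function(iccs, threshold = 0.75) {
  iccs <- iccs[!is.na(iccs)]
  if (length(iccs) < 2) {
    abort_rfd("need at least 2 ICC values", "rfdtools_too_few_pairs")
  }
  q <- stats::quantile(iccs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    median = round_half_away(q[2], 2),
    iqr_25 = round_half_away(q[1], 2),
    iqr_75 = round_half_away(q[3], 2),
    n_below_threshold = sum(iccs < threshold),
    n = length(iccs)
  )
}

#' One-stop reliability statistics for a paired comparison
#'
#' Convenience wrapper combining [icc_2_1()], [sem_abs()]/[sem_pct()] and
#' [mdc()] for one session-1 vs session-2 (or rater/device) pair, the way
#' reliability tables report them.
#'
#' @inheritParams pearson_ci
#' @param mdc_variant Passed to [mdc()].
#' @param mean_ref `"session1"` (default) or `"pooled"`: which mean the
#'   percent SEM/MDC are expressed against.
#' @param correlations Also include Pearson and concordance coefficients.
#' @return One-row tibble of all statistics.
#' @export
reliability_stats <- function(x, y, mdc_variant = c("sqrt2", "plain"),
                              mean_ref = c("session1", "pooled"),
                              correlations = FALSE) {
  mdc_variant <- match.arg(mdc_variant)
  mean_ref <- match.arg(mean_ref)
  p <- check_pairs(x, y)
  ic <- icc_2_1(p$x, p$y)
  sd1 <- stats::sd(p$x)
  m_ref <- switch(mean_ref, session1 = mean(p$x),
                  pooled = mean(c(p$x, p$y)))
  s_abs <- sem_abs(sd1, ic$icc)
  out <- tibble::tibble(
    n = p$n,
    mean1 = mean(p$x), sd1 = sd1,
    mean2 = mean(p$y), sd2 = stats::sd(p$y),
    icc = ic$icc, icc_lo = ic$icc_lo, icc_hi = ic$icc_hi,
    sem_abs = s_abs,
    sem_pct = 100 * s_abs / m_ref,
    mdc_abs = mdc(s_abs, mdc_variant),
    mdc_pct = mdc(100 * s_abs / m_ref, mdc_variant),
    mdc_variant = mdc_variant,
    band = as.character(classify_coefficient(max(min(ic$icc, 1), -1)))
  )
  if (correlations) {
    pr <- pearson_ci(p$x, p$y)
    cc <- lin_ccc(p$x, p$y)
    out <- dplyr::bind_cols(out, pr[, c("r", "r_lo", "r_hi")],
                            cc[, c("rc", "rc_lo", "rc_hi")])
  }
  out
}
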