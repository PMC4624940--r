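# Independent oracles used across tests. These deliberately take the slow,
# obvious route so they stay independent of the package implementation.

# O(n * w) exhaustive moving-window search
brute_force_moving_window <- function(time, force, window_ms) {
  dt <- stats::median(diff(time))
  w <- round(window_ms / 1000 / dt)
  best <- -Inf
  for (i in seq_len(length(force) - w)) {
    s <- (force[i + w] - force[i]) / (w * dt)
    if (s > best) best <- s
  }
  best
}

# ICC(2,1) mean squares via stats::aov on the long layout
aov_icc_2_1 <- function(x, y) {
  n <- length(x)
  long <- data.frame(val = c(x, y),
                     subj = factor(rep(seq_len(n), 2)),
                     occ = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(val ~ subj + occ, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# first-crossing time of `level` on a piecewise-linear curve, by brute
# scan with interpolation
piecewise_crossing <- function(time, force, level) {
  for (i in seq_len(length(force) - 1)) {
    if (force[i] < level && force[i + 1] >= level) {
      frac <- (level - force[i]) / (force[i + 1] - force[i])
      return(time[i] + frac * (time[i + 1] - time[i]))
    }
  }
  NA_real_
}

logistic_force <- function(t, f_max = 50, k = 20, t0 = 1) {
  f_max / (1 + exp(-k * (t - t0)))
}

# a random plausible rise-to-plateau trace (monotone base + noise)
random_trace <- function(n = 600, rate = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, by = 1 / rate, length.out = n)
  base <- cumsum(abs(rnorm(n, 0.05, 0.05)))
  force_trace(t, base + rnorm(n, 0, 0.2), "custom", nominal_rate = rate)
}

make_ramp <- function(slope = 25, peak = 50, rate = 1000) {
  t <- seq(0, peak / slope, by = 1 / rate)
  force_trace(t, slope * t, "custom", nominal_rate = rate)
}
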