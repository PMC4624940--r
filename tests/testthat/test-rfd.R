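test_that("peak force takes the highest sample over trials with earliest-tie rule", {
  r1 <- make_ramp(peak = 41.9)
  r2 <- make_ramp(peak = 44.3)
  pk <- peak_force(trial_set(list(r1, r2)))
  expect_equal(pk$peak_force, 44.3)
  expect_equal(pk$trial, 2)

  const <- force_trace(seq(0, 1, by = 0.001), rep(10, 1001), "stable_1000hz")
  pk2 <- peak_force(const)
  expect_equal(pk2$peak_force, 10)
  expect_equal(pk2$time, 0) # earliest tie

  expect_error(peak_force(structure(list(trials = list()), class = "trial_set")),
               class = "rfdtools_empty_trialset")

  # time reversal leaves peak force unchanged
  tr <- random_trace(seed = 99)
  rev_tr <- force_trace(tr$time, rev(tr$force), "custom")
  expect_equal(peak_force(tr)$peak_force, peak_force(rev_tr)$peak_force)
})

test_that("time to peak runs from the first sample to the first maximum", {
  ramp <- make_ramp(slope = 25, peak = 50) # 2 s rise
  expect_equal(time_to_peak(ramp), 2)
  const <- force_trace(c(0, 0.5, 1), c(3, 3, 3))
  expect_equal(time_to_peak(const), 0)
  # noiseless logistic is monotone: peak at the last sample (2 s trial,
  # short enough that the plateau has not saturated in double precision)
  tr <- simulate_trace(logistic_profile(noise_sd = 0, duration = 2),
                       "stable_1000hz")
  expect_equal(time_to_peak(tr), max(tr$time))
})

test_that("percent-window RFD matches closed-form and piecewise oracles", {
  ramp <- make_ramp(slope = 25, peak = 50)
  for (b in list(c(20, 80), c(5, 95), c(40, 60))) {
    expect_equal(rfd_percent_window(ramp, b[1], b[2]), 25, tolerance = 1e-9)
  }

  # logistic closed form: crossings at t0 + log(p/(1-p))/k
  pr <- logistic_profile(f_max = 50, k = 20, t0 = 1, noise_sd = 0)
  tr <- simulate_trace(pr, "stable_1000hz")
  expect_equal(rfd_percent_window(tr, 5, 95),
               0.9 * 50 / (2 * log(19) / 20), tolerance = 1e-3)
  expect_equal(logistic_percent_rfd(pr, 5, 95), 0.9 * 50 / (2 * log(19) / 20))

  # two-phase ramp: slope 10 then 40 kg/s, breakpoint at 50% of peak
  t <- seq(0, 2.5 + 0.625, by = 0.001)
  f <- ifelse(t <= 2.5, 10 * t, 25 + 40 * (t - 2.5))
  two <- force_trace(t, f, "custom")
  lo_t <- piecewise_crossing(t, f, 0.40 * max(f))
  hi_t <- piecewise_crossing(t, f, 0.60 * max(f))
  expect_equal(rfd_percent_window(two, 40, 60),
               0.2 * max(f) / (hi_t - lo_t), tolerance = 1e-9)

  # threshold never crossed before the first peak -> flagged NA, no error
  spike <- force_trace(seq(0, 0.02, by = 0.001),
                       c(10, rep(c(1, 2), 10)), "custom")
  expect_true(is.na(rfd_percent_window(spike, 20, 80)))
})

test_that("moving-window RFD equals the brute-force search exactly", {
  ramp <- make_ramp(slope = 25, peak = 50)
  for (w in c(10, 20, 50, 100, 200)) {
    expect_equal(rfd_moving_window(ramp, w)$rfd, 25, tolerance = 1e-9)
  }

  # exhaustive-oracle equivalence on random traces
  for (s in 1:25) {
    tr <- random_trace(n = 500 + s * 7, seed = s)
    for (w in c(10, 50, 200)) {
      expect_identical(rfd_moving_window(tr, w)$rfd,
                       brute_force_moving_window(tr$time, tr$force, w))
    }
  }

  # logistic: the peak 200 ms window is the chord centred at t0
  pr <- logistic_profile(f_max = 50, k = 20, t0 = 1, noise_sd = 0)
  tr <- simulate_trace(pr, "stable_1000hz")
  mw <- rfd_moving_window(tr, 200)
  expect_equal(mw$rfd, logistic_chord_rfd(pr, 0.2), tolerance = 1e-3)
  expect_equal(mw$start_time + 0.1, pr$t0, tolerance = 2e-3)

  expect_error(rfd_moving_window(make_ramp(peak = 2, slope = 25), 200),
               class = "rfdtools_too_short")
})

test_that("RFD obeys window-ordering, offset and scaling laws", {
  for (s in 1:10) {
    tr <- random_trace(seed = 100 + s)
    vals <- vapply(c(10, 20, 50, 100, 200),
                   function(w) rfd_moving_window(tr, w)$rfd, numeric(1))
    # a long window's mean slope is an average of short-window slopes
    expect_true(all(diff(vals) <= 1e-12))

    off <- force_trace(tr$time, tr$force + 7.5, "custom")
    sc <- force_trace(tr$time, tr$force * 3, "custom")
    expect_equal(rfd_moving_window(off, 50)$rfd, rfd_moving_window(tr, 50)$rfd)
    expect_equal(rfd_moving_window(sc, 50)$rfd, 3 * rfd_moving_window(tr, 50)$rfd)
  }

  # sigmoid rise: mid-rise percent window is steeper than the full window
  pr <- logistic_profile(noise_sd = 0)
  tr <- simulate_trace(pr, "stable_1000hz")
  expect_gte(rfd_percent_window(tr, 40, 60), rfd_percent_window(tr, 5, 95))

  # offset invariance / scale equivariance for the percent-window family
  # holds when thresholds reference the rise above a zero baseline
  sc2 <- force_trace(tr$time, tr$force * 2, "custom")
  expect_equal(rfd_percent_window(sc2, 20, 80),
               2 * rfd_percent_window(tr, 20, 80), tolerance = 1e-9)
})

test_that("compute_battery aggregates trials by the configured rule", {
  r <- make_ramp(slope = 25, peak = 50)
  res <- compute_battery(trial_set(list(r, r)))
  agg <- tidyr::pivot_wider(res$aggregate, names_from = "metric",
                            values_from = "value")
  expect_equal(agg$peak_force_kg, 50)
  expect_equal(agg$rfd_mw_200ms, 25, tolerance = 1e-9)
  # identical trials: aggregate equals the per-trial value for every method
  per <- tidyr::pivot_wider(res$per_trial, names_from = "metric",
                            values_from = "value")
  expect_equal(unlist(per[1, -1]), unlist(per[2, -1]))

  # max rule across different trials
  pr1 <- logistic_profile(f_max = 50, k = 18, noise_sd = 0)
  pr2 <- logistic_profile(f_max = 48, k = 16, noise_sd = 0)
  t1 <- simulate_trace(pr1, "stable_1000hz")
  t2 <- simulate_trace(pr2, "stable_1000hz")
  res2 <- compute_battery(trial_set(list(t1, t2)))
  v <- function(tab, m) tab$value[tab$metric == m]
  expect_equal(v(res2$aggregate, "rfd_mw_200ms"),
               max(v(res2$per_trial, "rfd_mw_200ms")))
  res_mean <- compute_battery(trial_set(list(t1, t2)), aggregate = "mean")
  expect_equal(v(res_mean$aggregate, "rfd_mw_200ms"),
               mean(v(res_mean$per_trial, "rfd_mw_200ms")))

  # full noiseless battery reproduces the analytic logistic values within 1%
  pp <- preprocess_trace(simulate_trace(pr1, "unstable_100hz", seed = 8))
  res3 <- compute_battery(trial_set(list(pp)))
  expect_equal(v(res3$aggregate, "rfd_mw_200ms"),
               logistic_chord_rfd(pr1, 0.2), tolerance = 0.01)
  expect_equal(v(res3$aggregate, "rfd_pct_5_95"),
               logistic_percent_rfd(pr1, 5, 95), tolerance = 0.01)
  expect_equal(v(res3$aggregate, "rfd_pct_40_60"),
               logistic_percent_rfd(pr1, 40, 60), tolerance = 0.01)
  expect_equal(v(res3$aggregate, "peak_force_kg"), 50, tolerance = 0.01)

  # tidy/glance accessors
  td <- tidy(res3)
  expect_true(all(c("participant", "trial", "metric", "value") %in% names(td)))
  gl <- glance(res3)
  expect_equal(gl$n_trials, 1)
})
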