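#' Logistic contraction profile
#'
#' The synthetic model of a maximal isometric contraction: a logistic rise
#' `F(t) = baseline + f_max / (1 + exp(-k (t - t0)))` from rest to a
#' steady plateau, over a 3-5 s effort (default 4 s). The closed forms
#' used as test oracles: instantaneous peak RFD `f_max * k / 4` at `t0`;
#' the `p`-percent-of-plateau crossing time `t0 + log(p / (1 - p)) / k`;
#' the width-`w` chord slope at `t0`, `f_max * tanh(k * w / 4) / w`.
#' Optional additives: Gaussian measurement noise and a brief initial
#' contact transient (half-sine bump) emulating placement of the device.
#'
#' @param f_max Plateau force above baseline, kg.
#' @param k Steepness, 1/s.
#' @param t0 Inflection time, s (0 < t0 < duration).
#' @param baseline Resting force, kg.
#' @param duration Trial length, s (default 4).
#' @param noise_sd Gaussian measurement noise SD, kg.
#' @param artifact `NULL` or `c(amplitude_kg, duration_ms)` contact bump
#'   at the start of the trial.
#' @return A `logistic_profile` list with function `f(t)` attached.
#' @export
logistic_profile <- function(f_max = 50, k = 20, t0 = 1, baseline = 0,
                             duration = 4, noise_sd = 0, artifact = NULL) {
  if (f_max <= 0 || k <= 0 || t0 <= 0 || t0 >= duration) {
    abort_rfd("need f_max > 0, k > 0, 0 < t0 < duration",
              "rfdtools_invalid_spec")
  }
  f <- function(t) baseline + f_max / (1 + exp(-k * (t - t0)))
  structure(list(f_max = f_max, k = k, t0 = t0, baseline = baseline,
                 duration = duration, noise_sd = noise_sd,
                 artifact = artifact, f = f),
            class = "logistic_profile")
}

#' @rdname logistic_profile
#' @param profile A `logistic_profile`.
#' @param window_s Chord width in seconds.
#' @export
logistic_chord_rfd <- function(profile, window_s) {
  profile$f_max * tanh(profile$k * window_s / 4) / window_s
}

#' @rdname logistic_profile
#' @param lo,hi Percent-of-plateau bounds.
#' @export
logistic_percent_rfd <- function(profile, lo, hi) {
  tcross <- function(p) log(p / (1 - p)) / profile$k
  (hi - lo) / 100 * profile$f_max / (tcross(hi / 100) - tcross(lo / 100))
}

device_time_grid <- function(device_profile, duration) {
  switch(device_profile,
    stable_40hz = seq(0, duration, by = 1 / 40),
    stable_1000hz = seq(0, duration, by = 1 / 1000),
    unstable_100hz = {
      nominal <- seq(0, duration, by = 0.01)
      jitter <- stats::runif(length(nominal), -0.003, 0.003)
      jitter[1] <- 0 # the first sample anchors t = 0
      sort(pmax(nominal + jitter, 0))
    },
    abort_rfd(sprintf("no built-in time grid for profile '%s'", device_profile),
              "rfdtools_invalid_spec")
  )
}

#' Simulate a force trace on a device's sampling grid
#'
#' Samples the profile's force curve on the device's time grid and adds
#' i.i.d. Gaussian measurement noise. The unstable ~100 Hz grid uses
#' 10 ms nominal intervals with uniform +/-3 ms clock jitter (sorted,
#' first sample anchored at 0). Deterministic given `seed`.
#'
#' @param profile A [logistic_profile()].
#' @param device_profile `"stable_40hz"`, `"unstable_100hz"` or
#'   `"stable_1000hz"`.
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @param metadata Metadata list for the trace.
#' @return A [force_trace()].
#' @export
simulate_trace <- function(profile, device_profile = "stable_1000hz",
                           seed = NULL, metadata = list()) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  time <- device_time_grid(device_profile, profile$duration)
  force <- profile$f(time)
  if (!is.null(profile$artifact)) {
    amp <- profile$artifact[1]
    dur_s <- profile$artifact[2] / 1000
    in_bump <- time <= dur_s
    force[in_bump] <- force[in_bump] + amp * sin(pi * time[in_bump] / dur_s)
  }
  if (profile$noise_sd > 0) {
    force <- force + stats::rnorm(length(time), 0, profile$noise_sd)
  }
  force_trace(time, force, device_profile = device_profile,
              metadata = metadata, rate_tol = 0.02)
}

#' Cohort specification for simulated measurement tables
#'
#' Describes a multi-factor reliability cohort with additive Gaussian
#' variance components. Rater, device and session effects are drawn per
#' subject-by-factor combination (subject-specific interaction effects),
#' so for any paired test-retest design within a fixed rater and device
#' the theoretical ICC has the closed form
#' `(s2_subject + s2_rater + s2_device) /
#'  (s2_subject + s2_rater + s2_device + s2_session + s2_error)`.
#'
#' @param n_subjects Number of participants.
#' @param muscles,raters,devices,sessions Factor levels (character).
#' @param grand_means Named numeric: mean value per muscle.
#' @param s2_subject,s2_rater,s2_device,s2_session,s2_error Variance
#'   components (units^2, all >= 0).
#' @param device_offsets Optional named numeric: fixed additive bias per
#'   device (e.g. a criterion device reading systematically higher).
#' @param hetero_sd_frac If > 0, adds heteroscedastic noise with SD equal
#'   to this fraction of the cell's expected value (exercises the
#'   regression-based Bland-Altman branch).
#' @param metric Metric label written into the table.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 30,
                        muscles = muscle_codes(),
                        raters = c("A", "B"),
                        devices = c("Lafayette", "Hoggan", "KinCom"),
                        sessions = c("1", "2"),
                        grand_means = NULL,
                        s2_subject = 9, s2_rater = 0, s2_device = 0,
                        s2_session = 0, s2_error = 1,
                        device_offsets = NULL,
                        hetero_sd_frac = 0,
                        metric = "peak_force_kg") {
  if (any(c(s2_subject, s2_rater, s2_device, s2_session, s2_error) < 0)) {
    abort_rfd("variance components must be >= 0", "rfdtools_invalid_spec")
  }
  grand_means <- grand_means %||%
    stats::setNames(rep(30, length(muscles)), muscles)
  structure(list(n_subjects = n_subjects, muscles = muscles,
                 raters = raters, devices = devices, sessions = sessions,
                 grand_means = grand_means,
                 s2_subject = s2_subject, s2_rater = s2_rater,
                 s2_device = s2_device, s2_session = s2_session,
                 s2_error = s2_error,
                 device_offsets = device_offsets,
                 hetero_sd_frac = hetero_sd_frac,
                 metric = metric),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @export
theoretical_icc <- function(spec) {
  num <- spec$s2_subject + spec$s2_rater + spec$s2_device
  num / (num + spec$s2_session + spec$s2_error)
}

#' Simulate a measurement cohort with known ground truth
#'
#' Draws every variance component per [cohort_spec()] and assembles the
#' long-format measurement table
#' `value = mu_muscle + u_subject + v_(subject,rater) + w_(subject,device)
#'  + s_(subject,session) + e`, optionally plus fixed device offsets and
#' heteroscedastic noise. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return A list: `table` (a [as_measurement_table()]) and `components`
#'   (the realised random effects, for ground-truth checks).
#' @export
simulate_cohort <- function(spec, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  subjects <- sprintf("P%02d", seq_len(spec$n_subjects))
  draw <- function(keys, s2) {
    stats::setNames(stats::rnorm(length(keys), 0, sqrt(s2)), keys)
  }
  comp <- list()
  for (mus in spec$muscles) {
    comp[[mus]] <- list(
      subject = draw(subjects, spec$s2_subject),
      rater = draw(as.vector(outer(subjects, spec$raters, paste, sep = ".")),
                   spec$s2_rater),
      device = draw(as.vector(outer(subjects, spec$devices, paste, sep = ".")),
                    spec$s2_device),
      session = draw(as.vector(outer(subjects, spec$sessions, paste, sep = ".")),
                     spec$s2_session)
    )
  }
  grid <- tidyr::expand_grid(
    participant = subjects, muscle = spec$muscles, device = spec$devices,
    rater = spec$raters, session = spec$sessions
  )
  mu <- spec$grand_means[grid$muscle]
  eff <- numeric(nrow(grid))
  for (mus in spec$muscles) {
    i <- grid$muscle == mus
    cm <- comp[[mus]]
    eff[i] <- cm$subject[grid$participant[i]] +
      cm$rater[paste(grid$participant[i], grid$rater[i], sep = ".")] +
      cm$device[paste(grid$participant[i], grid$device[i], sep = ".")] +
      cm$session[paste(grid$participant[i], grid$session[i], sep = ".")]
  }
  value <- mu + eff + stats::rnorm(nrow(grid), 0, sqrt(spec$s2_error))
  if (!is.null(spec$device_offsets)) {
    off <- spec$device_offsets[grid$device]
    off[is.na(off)] <- 0
    value <- value + off
  }
  if (spec$hetero_sd_frac > 0) {
    value <- value + stats::rnorm(nrow(grid), 0,
                                  spec$hetero_sd_frac * abs(mu + eff))
  }
  tab <- dplyr::mutate(grid, metric = spec$metric, value = value)
  list(table = as_measurement_table(tab, check_muscles = FALSE),
       components = comp, spec = spec)
}
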