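#' Rate-of-force-development method specifications
#'
#' Builds the table of RFD algorithms to run over a trial. Three families
#' are supported:
#' \describe{
#'   \item{time_to_peak}{time from the first recorded sample to the first
#'     maximal force sample (seconds; not a slope).}
#'   \item{percent_window}{slope between the first crossings of two force
#'     thresholds expressed as percentages of the trial's peak force; the
#'     force interval is fixed, the duration varies.}
#'   \item{moving_window}{maximum mean slope over all fixed-length windows
#'     slid sample-by-sample along the whole trial; the duration is fixed,
#'     the position varies.}
#' }
#' The defaults enumerate the standard comparison battery: time to peak,
#' the eight symmetric percent windows 5-95 ... 40-60, and moving windows
#' of 10, 20, 50, 100 and 200 ms - 14 methods in all.
#'
#' @param percents List of `c(lo, hi)` percent bounds, `0 < lo < hi < 100`.
#' @param windows_ms Moving-window lengths in milliseconds.
#' @param include_time_to_peak Include the time-to-peak method.
#' @return A tibble with columns `method` (label), `family`, `lo`, `hi`,
#'   `window_ms`.
#' @export
rfd_methods <- function(percents = list(c(5, 95), c(10, 90), c(15, 85),
                                        c(20, 80), c(25, 75), c(30, 70),
                                        c(35, 65), c(40, 60)),
                        windows_ms = c(10, 20, 50, 100, 200),
                        include_time_to_peak = TRUE) {
  rows <- list()
  if (include_time_to_peak) {
    rows <- c(rows, list(tibble::tibble(method = "time_to_peak_s",
                                        family = "time_to_peak",
                                        lo = NA_real_, hi = NA_real_,
                                        window_ms = NA_real_)))
  }
  for (p in percents) {
    if (!(p[1] > 0 && p[1] < p[2] && p[2] < 100)) {
      abort_rfd("percent bounds must satisfy 0 < lo < hi < 100",
                "rfdtools_invalid_spec")
    }
    rows <- c(rows, list(tibble::tibble(
      method = sprintf("rfd_pct_%g_%g", p[1], p[2]),
      family = "percent_window", lo = p[1], hi = p[2],
      window_ms = NA_real_)))
  }
  for (w in windows_ms) {
    if (w <= 0) abort_rfd("window_ms must be positive", "rfdtools_invalid_spec")
    rows <- c(rows, list(tibble::tibble(
      method = sprintf("rfd_mw_%gms", w),
      family = "moving_window", lo = NA_real_, hi = NA_real_,
      window_ms = w)))
  }
  dplyr::bind_rows(rows)
}

#' Peak force over a trial set
#'
#' Muscle strength is the highest force sample recorded over all trials of
#' the set (conventionally two maximal contractions). Ties go to the
#' earliest sample of the lowest-index trial.
#'
#' @param trials A [trial_set()] of preprocessed traces, or a single
#'   `force_trace`.
#' @return A one-row tibble: `peak_force` (kg), `trial` (index), `time` (s).
#' @export
peak_force <- function(trials) {
  if (inherits(trials, "force_trace")) trials <- trial_set(list(trials))
  if (!length(trials$trials)) {
    abort_rfd("empty trial set", "rfdtools_empty_trialset")
  }
  best <- purrr::imap(trials$trials, function(tr, i) {
    j <- which.max(tr$force) # which.max returns the first maximum
    tibble::tibble(peak_force = tr$force[j], trial = i, time = tr$time[j])
  })
  best <- dplyr::bind_rows(best)
  best[which.max(best$peak_force), ]
}

#' Time to peak force
#'
#' Seconds from the first recorded sample to the first maximal force
#' sample. No contraction-onset detection is performed: the clock starts
#' at the first sample.
#'
#' @param trace A preprocessed [force_trace()].
#' @return Time to peak in seconds.
#' @export
time_to_peak <- function(trace) {
  validate_force_trace(trace)
  trace$time[which.max(trace$force)] - trace$time[1]
}

# first upward crossing of `level` on f over the index range 1..i_end;
# linearly interpolated time, or NA if never crossed
first_crossing <- function(time, f, level, i_end) {
  if (f[1] >= level) return(time[1])
  idx <- which(f[2:i_end] >= level & f[1:(i_end - 1)] < level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  frac <- (level - f[i]) / (f[i + 1] - f[i])
  time[i] + frac * (time[i + 1] - time[i])
}

#' Percent-of-peak-force RFD
#'
#' Slope of the force rise between two thresholds set at `lo`% and `hi`%
#' of the trial's peak force: `(hi - lo)% x peak / (t_hi - t_lo)`, where
#' the threshold times are the first upward crossings (linearly
#' interpolated between bracketing samples) on the rise to the first force
#' maximum. If either threshold is never crossed before the peak (e.g. a
#' contact artifact larger than the threshold), the value is flagged
#' missing (`NA`) rather than raising an error.
#'
#' @param trace A preprocessed [force_trace()].
#' @param lo,hi Percent bounds, `0 < lo < hi < 100`.
#' @param subslope If `TRUE`, search for the maximal moving-window slope
#'   restricted to the threshold-to-threshold segment instead of the
#'   endpoint slope (an alternative reading of "peak RFD between
#'   percentages"); the endpoint slope is the primary definition.
#' @return RFD in kg/s, or `NA` when flagged missing.
#' @export
rfd_percent_window <- function(trace, lo, hi, subslope = FALSE) {
  validate_force_trace(trace)
  if (!(lo > 0 && lo < hi && hi < 100)) {
    abort_rfd("percent bounds must satisfy 0 < lo < hi < 100",
              "rfdtools_invalid_spec")
  }
  f <- trace$force
  i_peak <- which.max(f)
  peak <- f[i_peak]
  if (i_peak < 2) return(NA_real_)
  t_lo <- first_crossing(trace$time, f, lo / 100 * peak, i_peak)
  t_hi <- first_crossing(trace$time, f, hi / 100 * peak, i_peak)
  if (is.na(t_lo) || is.na(t_hi) || t_hi <= t_lo) return(NA_real_)
  if (!subslope) {
    return((hi - lo) / 100 * peak / (t_hi - t_lo))
  }
  seg <- which(trace$time >= t_lo & trace$time <= t_hi)
  if (length(seg) < 2) return((hi - lo) / 100 * peak / (t_hi - t_lo))
  max(diff(f[seg]) / diff(trace$time[seg]))
}

#' Moving-window (successive time interval) peak RFD
#'
#' Slides a fixed-length window sample-by-sample along the whole trial
#' (samples 1..1+w, 2..2+w, ...) and returns the maximum mean slope
#' `(F[i+w] - F[i]) / (w * dt)`. The search starts at the first recorded
#' sample and spans the full trial; ties go to the earliest window.
#'
#' @param trace A preprocessed, uniformly sampled [force_trace()].
#' @param window_ms Window length in milliseconds; converted to samples as
#'   `round(window_ms * rate / 1000)` (exact at 1000 Hz).
#' @return A one-row tibble: `rfd` (kg/s), `start_time` (s), `window_ms`.
#' @export
rfd_moving_window <- function(trace, window_ms) {
  validate_force_trace(trace)
  if (!is_uniform_trace(trace)) {
    abort_rfd("moving-window RFD requires a uniformly sampled trace",
              "rfdtools_nonuniform")
  }
  dt <- stats::median(diff(trace$time))
  w <- round(window_ms / 1000 / dt)
  if (w < 1) {
    abort_rfd("window shorter than one sample interval", "rfdtools_invalid_spec")
  }
  n <- nrow(trace)
  if (n <= w) {
    abort_rfd(sprintf("trace (%d samples) not longer than window (%d samples)",
                      n, w), "rfdtools_too_short")
  }
  f <- trace$force
  slopes <- (f[(w + 1):n] - f[1:(n - w)]) / (w * dt)
  i <- which.max(slopes) # earliest tie
  tibble::tibble(rfd = slopes[i], start_time = trace$time[i],
                 window_ms = window_ms)
}

rfd_one_method <- function(trace, row, subslope = FALSE) {
  switch(row$family,
    time_to_peak = time_to_peak(trace),
    percent_window = rfd_percent_window(trace, row$lo, row$hi,
                                        subslope = subslope),
    moving_window = rfd_moving_window(trace, row$window_ms)$rfd,
    abort_rfd(sprintf("unknown RFD family '%s'", row$family),
              "rfdtools_invalid_spec")
  )
}

#' Full strength and power battery for a trial set
#'
#' Computes peak force (over all trials) and every requested RFD method
#' per trial, plus an across-trials aggregate. The aggregate mirrors the
#' peak-force rule by default (maximum over trials); `"mean"` and
#' `"best_trial"` (the trial with the higher peak force) are alternatives.
#' Flagged-missing per-trial values propagate as `NA` without aborting the
#' battery (the `max`/`mean` aggregates drop them when at least one trial
#' has a value).
#'
#' @param trials A [trial_set()] of preprocessed traces.
#' @param methods Method table from [rfd_methods()].
#' @param aggregate Across-trials rule: `"max"` (default), `"mean"`, or
#'   `"best_trial"`.
#' @param subslope Passed to [rfd_percent_window()].
#' @return A `strength_power_result`: list with `key`, `peak` (from
#'   [peak_force()]), `per_trial` and `aggregate` tibbles in long
#'   (`metric`, `value`) format.
#' @export
compute_battery <- function(trials, methods = rfd_methods(),
                            aggregate = c("max", "mean", "best_trial"),
                            subslope = FALSE) {
  aggregate <- match.arg(aggregate)
  if (inherits(trials, "force_trace")) trials <- trial_set(list(trials))
  pk <- peak_force(trials)
  per_trial <- purrr::imap(trials$trials, function(tr, ti) {
    vals <- purrr::map_dbl(seq_len(nrow(methods)), function(mi) {
      rfd_one_method(tr, methods[mi, ], subslope = subslope)
    })
    tibble::tibble(trial = ti, metric = methods$method, value = vals)
  })
  per_trial <- dplyr::bind_rows(per_trial)

  agg <- per_trial |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(value = agg_rule(.data$value, .data$trial, aggregate,
                                      best = pk$trial),
                     .groups = "drop")
  agg <- dplyr::bind_rows(
    tibble::tibble(metric = "peak_force_kg", value = pk$peak_force),
    agg
  )
  structure(list(key = trials$key, peak = pk,
                 per_trial = per_trial, aggregate = agg,
                 aggregate_rule = aggregate),
            class = "strength_power_result")
}

agg_rule <- function(values, trial_idx, rule, best) {
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  switch(rule,
    max = max(values[ok]),
    mean = mean(values[ok]),
    best_trial = {
      v <- values[trial_idx == best]
      if (length(v) && !is.na(v[1])) v[1] else max(values[ok])
    }
  )
}

#' @export
print.strength_power_result <- function(x, ...) {
  cat(sprintf("<strength_power_result> peak force %.2f kg (trial %d at %.3f s); %d trial(s), %d methods; aggregate = %s\n",
              x$peak$peak_force, x$peak$trial, x$peak$time,
              length(unique(x$per_trial$trial)),
              length(unique(x$per_trial$metric)), x$aggregate_rule))
  print(tidyr::pivot_wider(x$aggregate, names_from = "metric",
                           values_from = "value"))
  invisible(x)
}
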