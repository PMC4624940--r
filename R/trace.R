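#' Force-trace objects
#'
#' A force trace is a tibble with columns `time` (seconds, strictly
#' increasing, starting at the first recorded sample) and `force`
#' (kilograms), carrying the recording device's sampling profile as
#' attributes. Three named profiles mirror common dynamometers: a stable
#' 40 Hz hand-held device, an unstable ~100 Hz hand-held device with
#' jittered sample clocks, and a stable 1000 Hz fixed laboratory
#' dynamometer.
#'
#' @param time Numeric vector of sample times in seconds; non-negative and
#'   strictly increasing.
#' @param force Numeric vector of force values in kilograms, same length as
#'   `time`; all values must be finite.
#' @param device_profile One of `"stable_40hz"`, `"unstable_100hz"`,
#'   `"stable_1000hz"`, `"custom"`.
#' @param nominal_rate Nominal sampling rate in Hz. Defaults to the rate
#'   implied by the named profile.
#' @param metadata Named list of free-form strings (participant, muscle,
#'   device, rater, session, trial ...).
#' @param rate_tol For stable profiles, the maximum allowed deviation of a
#'   successive sampling interval from `1/nominal_rate`, as a fraction of
#'   the nominal interval.
#' @return A `force_trace`: a tibble with columns `time` and `force` and
#'   attributes `device_profile`, `nominal_rate`, `metadata`.
#' @examples
#' tr <- force_trace(seq(0, 1, by = 0.025), seq(0, 50, length.out = 41),
#'                   device_profile = "stable_40hz")
#' trace_rate(tr)
#' @export
force_trace <- function(time, force,
                        device_profile = c("custom", "stable_40hz",
                                           "unstable_100hz", "stable_1000hz"),
                        nominal_rate = NULL,
                        metadata = list(),
                        rate_tol = 0.01) {
  device_profile <- match.arg(device_profile)
  nominal_rate <- nominal_rate %||% switch(device_profile,
    stable_40hz = 40, unstable_100hz = 100, stable_1000hz = 1000,
    custom = infer_rate(time)
  )
  out <- tibble::new_tibble(
    list(time = as.double(time), force = as.double(force)),
    nrow = length(time),
    class = "force_trace",
    device_profile = device_profile,
    nominal_rate = nominal_rate,
    metadata = metadata
  )
  validate_force_trace(out, rate_tol = rate_tol)
}

infer_rate <- function(time) {
  if (length(time) < 2) return(NA_real_)
  1 / stats::median(diff(time))
}

#' Validate a force trace
#'
#' Checks the structural invariants: equal-length time and force columns
#' with at least 2 samples, strictly increasing non-negative times, finite
#' forces, and (for stable device profiles) successive intervals within
#' `rate_tol` of the nominal interval.
#'
#' @param x A `force_trace`.
#' @inheritParams force_trace
#' @return `x`, invisibly unchanged, or an error of class
#'   `rfdtools_invalid_trace`.
#' @export
validate_force_trace <- function(x, rate_tol = 0.01) {
  time <- x$time
  force <- x$force
  if (length(time) != length(force) || length(time) < 2) {
    abort_rfd("a force trace needs >= 2 samples with matching time and force lengths",
              "rfdtools_invalid_trace")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    abort_rfd("sample times must be finite and non-negative", "rfdtools_invalid_trace")
  }
  if (any(diff(time) <= 0)) {
    abort_rfd("sample times must be strictly increasing", "rfdtools_invalid_trace")
  }
  if (any(!is.finite(force))) {
    abort_rfd("force values must all be finite", "rfdtools_invalid_trace")
  }
  profile <- trace_profile(x)
  if (profile %in% c("stable_40hz", "stable_1000hz")) {
    nominal_dt <- 1 / trace_rate(x)
    dev <- abs(diff(time) - nominal_dt) / nominal_dt
    if (max(dev) > rate_tol) {
      abort_rfd(
        sprintf("profile '%s' requires stable sampling: interval deviates %.1f%% from 1/%g s",
                profile, 100 * max(dev), trace_rate(x)),
        "rfdtools_invalid_trace"
      )
    }
  }
  invisible(x)
}

#' @rdname force_trace
#' @param x A `force_trace`.
#' @export
trace_rate <- function(x) attr(x, "nominal_rate")

#' @rdname force_trace
#' @export
trace_profile <- function(x) attr(x, "device_profile") %||% "custom"

#' @rdname force_trace
#' @export
trace_metadata <- function(x) attr(x, "metadata") %||% list()

new_trace_like <- function(template, time, force,
                           device_profile = trace_profile(template),
                           nominal_rate = trace_rate(template)) {
  tibble::new_tibble(
    list(time = as.double(time), force = as.double(force)),
    nrow = length(time),
    class = "force_trace",
    device_profile = device_profile,
    nominal_rate = nominal_rate,
    metadata = trace_metadata(template)
  )
}

is_uniform_trace <- function(x, tol = 1e-6) {
  dt <- diff(x$time)
  length(dt) >= 1 && (max(dt) - min(dt)) <= tol * stats::median(dt)
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples, %.3f-%.3f s, profile %s (%g Hz nominal)\n",
              nrow(x), x$time[1], x$time[nrow(x)], trace_profile(x), trace_rate(x)))
  md <- trace_metadata(x)
  if (length(md)) {
    cat("  ", paste(names(md), unlist(md), sep = "=", collapse = " "), "\n")
  }
  NextMethod()
}

#' Bundle trials for one measurement cell
#'
#' A trial set holds the repeated contractions (typically two) recorded for
#' one participant x muscle x device x rater x session cell. All trials must
#' share the same key.
#'
#' @param trials List of `force_trace` objects (at least one).
#' @param participant,muscle,device,rater,session Key fields; if omitted,
#'   taken from the first trial's metadata.
#' @return A `trial_set`: list with elements `trials` (list of traces) and
#'   `key` (one-row tibble).
#' @export
trial_set <- function(trials, participant = NULL, muscle = NULL,
                      device = NULL, rater = NULL, session = NULL) {
  if (!length(trials)) {
    abort_rfd("a trial set needs at least one trial", "rfdtools_empty_trialset")
  }
  md <- trace_metadata(trials[[1]])
  key <- tibble::tibble(
    participant = as.character(participant %||% md$participant %||% NA),
    muscle = as.character(muscle %||% md$muscle %||% NA),
    device = as.character(device %||% md$device %||% NA),
    rater = as.character(rater %||% md$rater %||% NA),
    session = as.character(session %||% md$session %||% NA)
  )
  structure(list(trials = trials, key = key), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trial(s); key: %s\n", length(x$trials),
              paste(names(x$key), unlist(x$key), sep = "=", collapse = " ")))
  invisible(x)
}

#' Muscle-group codes
#'
#' The eight lower-limb muscle groups used throughout: ankle dorsiflexors
#' and plantarflexors, hip abductors/adductors/extensors/flexors, knee
#' extensors/flexors.
#'
#' @return Character vector of the eight codes.
#' @export
muscle_codes <- function() {
  c("ADF", "APF", "HAB", "HAD", "HE", "HF", "KE", "KF")
}
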