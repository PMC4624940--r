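#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-unit rows of a result
#' (per-trial RFD values, per-cell agreement statistics, per-pair
#' Bland-Altman points); `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name rfd-tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rfd-tidiers
#' @export
tidy.strength_power_result <- function(x, ...) {
  dplyr::bind_cols(x$key[rep(1, nrow(x$per_trial)), ], x$per_trial)
}

#' @rdname rfd-tidiers
#' @export
glance.strength_power_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = "value")
  dplyr::bind_cols(x$key, wide,
                   tibble::tibble(n_trials = length(unique(x$per_trial$trial)),
                                  aggregate_rule = x$aggregate_rule))
}

#' @rdname rfd-tidiers
#' @export
tidy.agreement_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$ba <- NULL
  out
}

#' @rdname rfd-tidiers
#' @export
glance.agreement_report <- function(x, ...) {
  d <- attr(x, "design")
  ok <- x[x$ok, , drop = FALSE]
  tibble::tibble(
    type = d$type,
    n_cells = nrow(x),
    n_ok = nrow(ok),
    median_icc = stats::median(ok$icc, na.rm = TRUE),
    min_icc = suppressWarnings(min(ok$icc, na.rm = TRUE)),
    max_icc = suppressWarnings(max(ok$icc, na.rm = TRUE))
  )
}

#' @rdname rfd-tidiers
#' @export
tidy.bland_altman <- function(x, ...) {
  x$data
}

#' @rdname rfd-tidiers
#' @export
glance.bland_altman <- function(x, ...) {
  if (x$kind == "standard") {
    tibble::tibble(kind = x$kind, n = x$n, bias = x$bias,
                   loa_low = x$loa_low, loa_high = x$loa_high,
                   proportional_bias_r = x$proportional_bias_r)
  } else {
    tibble::tibble(kind = x$kind, n = x$n,
                   bias_intercept = x$bias_line[1],
                   bias_slope = x$bias_line[2],
                   loa_low_intercept = x$loa_low_line[1],
                   loa_low_slope = x$loa_low_line[2],
                   loa_high_intercept = x$loa_high_line[1],
                   loa_high_slope = x$loa_high_line[2],
                   proportional_bias_r = x$proportional_bias_r)
  }
}
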