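#' Round half away from zero
#'
#' Commercial rounding as used when formatting agreement coefficients for
#' report parity: 0.925 rounds to 0.93, -0.925 to -0.93. Base R's `round()`
#' rounds half to even, which would give 0.92.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored as 0.92499999... from
  # decimal literals still round the way their printed form suggests
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# gravity constant for newton -> kilogram-force conversion
.g_standard <- 9.80665

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_rfd <- function(msg, class) {
  rlang::abort(msg, class = c(class, "rfdtools_error"))
}
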