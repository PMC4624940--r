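#' Plot a force trace
#'
#' Force-time curve with the peak-force sample marked.
#'
#' @param object A [force_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_trace <- function(object, ...) {
  j <- which.max(object$force)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::annotate("point", x = object$time[j], y = object$force[j],
                      colour = "red", size = 2) +
    ggplot2::labs(x = "time (s)", y = "force (kg)",
                  title = sprintf("%s trace, peak %.1f kg at %.2f s",
                                  trace_profile(object), object$force[j],
                                  object$time[j])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences against averages with the bias and 95% limits of agreement
#' (lines for the regression-based kind).
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$average, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "average of pair", y = "difference (x - y)",
                  title = sprintf("Bland-Altman (%s), n = %d",
                                  gsub("_", "-", object$kind), object$n)) +
    ggplot2::theme_minimal()
  if (object$kind == "standard") {
    p + ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
      ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                          linetype = "dashed", colour = "red")
  } else {
    p +
      ggplot2::geom_abline(intercept = object$bias_line[1],
                           slope = object$bias_line[2], colour = "blue") +
      ggplot2::geom_abline(intercept = object$loa_low_line[1],
                           slope = object$loa_low_line[2],
                           linetype = "dashed", colour = "red") +
      ggplot2::geom_abline(intercept = object$loa_high_line[1],
                           slope = object$loa_high_line[2],
                           linetype = "dashed", colour = "red")
  }
}

#' Plot a method-comparison summary
#'
#' Per-method distribution of per-muscle ICCs with the good-reliability
#' threshold.
#'
#' @param iccs_long Long tibble with columns `method`, `icc` (e.g. from
#'   [example_method_iccs()] or a [method_comparison()] input).
#' @param threshold Threshold line, default 0.75.
#' @return A ggplot.
#' @export
plot_method_comparison <- function(iccs_long, threshold = 0.75) {
  ggplot2::ggplot(iccs_long,
                  ggplot2::aes(x = .data$method, y = .data$icc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "test-retest ICC(2,1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
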