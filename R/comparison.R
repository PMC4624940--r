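#' Specify an agreement comparison over a measurement table
#'
#' A comparison design names the paired factor (the factor whose two
#' levels form the x/y pair within each subject) and the fixed factors
#' whose level combinations define the analysis cells. The four standard
#' designs:
#' \describe{
#'   \item{intra_rater}{pair sessions 1 vs 2 within (muscle, device,
#'     rater, metric); report ICC/SEM/MDC.}
#'   \item{inter_rater}{pair the two raters within (muscle, device,
#'     metric) at one session; report ICC/SEM/MDC plus Pearson and
#'     concordance.}
#'   \item{inter_device}{pair two devices within (muscle, rater, metric)
#'     at one session; report ICC/SEM/MDC plus correlations.}
#'   \item{validity}{pair a practical device against a criterion device;
#'     report ICC, correlations and Bland-Altman.}
#' }
#'
#' @param type One of `"intra_rater"`, `"inter_rater"`, `"inter_device"`,
#'   `"validity"`.
#' @param levels Character vector of the two levels of the paired factor,
#'   in (x, y) order; e.g. `c("1", "2")` sessions, two rater codes, or
#'   `c(device, criterion)`. `NULL` uses the first two levels found.
#' @param session For rater/device comparisons: which session to analyse
#'   (default `"1"`).
#' @param mdc_variant,mean_ref Passed to [reliability_stats()].
#' @return A `comparison_design` list.
#' @export
comparison_design <- function(type = c("intra_rater", "inter_rater",
                                       "inter_device", "validity"),
                              levels = NULL, session = "1",
                              mdc_variant = c("sqrt2", "plain"),
                              mean_ref = c("session1", "pooled")) {
  type <- match.arg(type)
  structure(list(
    type = type,
    paired_factor = switch(type, intra_rater = "session",
                           inter_rater = "rater", "device"),
    levels = levels,
    session = as.character(session),
    mdc_variant = match.arg(mdc_variant),
    mean_ref = match.arg(mean_ref)
  ), class = "comparison_design")
}

#' Run an agreement comparison over a measurement table
#'
#' Splits the table into analysis cells (muscle x metric x remaining fixed
#' factors), forms pairwise-complete subject pairs on the design's paired
#' factor, and computes the statistics attached to the design type:
#' ICC(2,1) with CI, SEM and MDC (absolute and percent) for reliability
#' designs, plus Pearson and Lin concordance for between-rater /
#' between-device designs, plus Bland-Altman (standard or
#' regression-based, auto-selected by the proportional-bias rule) for
#' validity designs. Cells with fewer than 3 complete pairs are flagged
#' (`ok = FALSE`) rather than fatal.
#'
#' @param table A [as_measurement_table()] (or coercible data frame).
#' @param design A [comparison_design()].
#' @return An `agreement_report`: tibble with one row per cell and a
#'   `designs` attribute; Bland-Altman objects in a list-column `ba` for
#'   validity designs.
#' @export
run_comparison <- function(table, design) {
  table <- as_measurement_table(table, check_muscles = FALSE)
  pf <- design$paired_factor
  if (design$type != "intra_rater") {
    table <- dplyr::filter(table, .data$session == design$session)
  }
  lv <- design$levels %||% sort(unique(table[[pf]]))[1:2]
  if (length(lv) != 2 || any(is.na(lv))) {
    abort_rfd("paired factor must have exactly two levels to compare",
              "rfdtools_invalid_spec")
  }
  cell_vars <- setdiff(measurement_key_cols, c("participant", pf))
  if (design$type != "intra_rater") cell_vars <- setdiff(cell_vars, "session")

  wide <- table |>
    dplyr::filter(.data[[pf]] %in% lv) |>
    dplyr::mutate(.side = ifelse(.data[[pf]] == lv[1], "x", "y")) |>
    dplyr::select(-dplyr::all_of(pf)) |>
    tidyr::pivot_wider(names_from = ".side", values_from = "value")
  if (!all(c("x", "y") %in% names(wide))) {
    abort_rfd("one of the paired levels has no data", "rfdtools_too_few_pairs")
  }

  cells <- wide |>
    dplyr::group_by(!!!rlang::syms(cell_vars)) |>
    tidyr::nest() |>
    dplyr::ungroup()

  with_corr <- design$type %in% c("inter_rater", "inter_device", "validity")
  with_ba <- design$type == "validity"

  stats_list <- purrr::map(cells$data, function(d) {
    n_ok <- sum(is.finite(d$x) & is.finite(d$y))
    if (n_ok < 3) {
      return(list(row = tibble::tibble(n = n_ok, ok = FALSE), ba = NULL))
    }
    row <- reliability_stats(d$x, d$y, mdc_variant = design$mdc_variant,
                             mean_ref = design$mean_ref,
                             correlations = with_corr)
    row$ok <- TRUE
    ba <- NULL
    if (with_ba) {
      ba <- bland_altman(d$x, d$y)
      row$ba_kind <- ba$kind
      row$ba_prop_r <- ba$proportional_bias_r
      if (ba$kind == "standard") {
        row$ba_bias <- ba$bias
        row$ba_loa_low <- ba$loa_low
        row$ba_loa_high <- ba$loa_high
      }
    }
    list(row = row, ba = ba)
  })

  out <- dplyr::bind_cols(
    cells[cell_vars],
    dplyr::bind_rows(purrr::map(stats_list, "row"))
  )
  out$ok[is.na(out$ok)] <- FALSE
  if (with_ba) out$ba <- purrr::map(stats_list, "ba")
  attr(out, "design") <- design
  attr(out, "levels") <- lv
  class(out) <- c("agreement_report", class(tibble::tibble()))
  out
}

#' Method-comparison summary across muscle groups
#'
#' Runs the test-retest (intra-rater) comparison for every RFD metric in
#' the table, collects one ICC per muscle group per metric, and summarises
#' each metric column with [summarize_method_column()]: the workflow used
#' to pick the most reliable RFD algorithm.
#'
#' @param table A measurement table with `session` 1 and 2 values.
#' @param threshold Reliability threshold for the below-count, default 0.75.
#' @param metrics Metrics to summarise; default all except peak force.
#' @return A tibble with one row per metric: the per-muscle ICC summary.
#' @export
method_comparison <- function(table, threshold = 0.75, metrics = NULL) {
  rep <- run_comparison(table, comparison_design("intra_rater"))
  rep <- dplyr::filter(rep, .data$ok)
  non_peak <- setdiff(unique(rep$metric), "peak_force_kg")
  metrics <- metrics %||% (if (length(non_peak)) non_peak else
                             unique(rep$metric))
  rep |>
    dplyr::filter(.data$metric %in% metrics) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(summarize_method_column(.data$icc, threshold = threshold),
                     .groups = "drop")
}
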