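#' Read a force trace from delimited text
#'
#' Reads one trial's force-time series from a CSV (or other delimited) file.
#' The file must provide a force column and either a time column in seconds
#' or a sample-index column (in which case `nominal_rate` synthesises times
#' as `index / nominal_rate` relative to the first sample). Force in
#' newtons is converted to kilogram-force by dividing by g = 9.80665.
#'
#' @param path Path to a delimited text file with a header row.
#' @param device_profile Sampling profile of the recording device; see
#'   [force_trace()].
#' @param column_map Named character vector mapping the roles
#'   `time_s`, `sample_idx`, `force_kg`, `force_n` to column names in the
#'   file. Defaults look for columns with those ISO names.
#' @param nominal_rate Sampling rate in Hz; required when only a
#'   sample-index column is present, otherwise defaults to the profile's
#'   rate.
#' @param metadata Named list merged into the trace metadata; columns of the
#'   file other than time/force are also captured (first value per column).
#' @param delim Field delimiter, default comma.
#' @return A validated [force_trace()].
#' @export
read_trace <- function(path,
                       device_profile = "custom",
                       column_map = NULL,
                       nominal_rate = NULL,
                       metadata = list(),
                       delim = ",") {
  if (!file.exists(path)) {
    abort_rfd(sprintf("trace file not found: %s", path), "rfdtools_io_error")
  }
  dat <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) abort_rfd(sprintf("cannot parse '%s': %s", path,
                                          conditionMessage(e)),
                                  "rfdtools_parse_error")
  )
  probs <- readr::problems(dat)
  if (nrow(probs) > 0) {
    abort_rfd(sprintf("malformed rows in '%s' at line(s) %s", path,
                      paste(unique(probs$row), collapse = ", ")),
              "rfdtools_parse_error")
  }
  map <- c(time_s = "time_s", sample_idx = "sample_idx",
           force_kg = "force_kg", force_n = "force_n")
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  pick <- function(role) {
    col <- map[[role]]
    if (!is.null(col) && col %in% names(dat)) dat[[col]] else NULL
  }

  force <- pick("force_kg")
  if (is.null(force)) {
    fn <- pick("force_n")
    if (is.null(fn)) {
      abort_rfd("no force column found (expected force_kg or force_n)",
                "rfdtools_parse_error")
    }
    force <- fn / .g_standard
  }
  if (!is.numeric(force)) {
    bad <- which(is.na(suppressWarnings(as.numeric(force))))
    abort_rfd(sprintf("non-numeric force value at data line %d",
                      if (length(bad)) bad[1] else NA_integer_),
              "rfdtools_parse_error")
  }

  time <- pick("time_s")
  if (is.null(time)) {
    idx <- pick("sample_idx")
    if (is.null(idx)) {
      abort_rfd("no time_s or sample_idx column found", "rfdtools_parse_error")
    }
    rate <- nominal_rate %||% switch(device_profile,
      stable_40hz = 40, unstable_100hz = 100, stable_1000hz = 1000, NULL)
    if (is.null(rate)) {
      abort_rfd("a nominal_rate is required to convert sample indices to seconds",
                "rfdtools_parse_error")
    }
    time <- (idx - idx[1]) / rate
  }

  extra_cols <- setdiff(names(dat), unname(map))
  extra <- purrr::map(dat[extra_cols], ~ as.character(.x[1]))
  force_trace(time, force,
              device_profile = device_profile,
              nominal_rate = nominal_rate,
              metadata = utils::modifyList(extra, metadata))
}

#' Write a force trace to CSV
#'
#' @param trace A [force_trace()].
#' @param path Output path; columns `time_s`, `force_kg`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::tibble(time_s = trace$time, force_kg = trace$force),
                   path, progress = FALSE)
  invisible(path)
}

measurement_key_cols <- c("participant", "muscle", "device", "rater",
                          "session", "metric")

#' Long-format measurement tables
#'
#' A measurement table holds one outcome value per
#' (participant, muscle, device, rater, session, metric) key: the
#' long-format layout in which reliability and validity comparisons are
#' expressed. `as_measurement_table()` validates a data frame; the reader
#' and writer round-trip the table through CSV exactly.
#'
#' @param x A data frame with the six key columns and `value`.
#' @param check_muscles If `TRUE` (default), muscle codes must be among
#'   [muscle_codes()].
#' @return A validated tibble of class `measurement_table`.
#' @export
as_measurement_table <- function(x, check_muscles = TRUE) {
  missing_cols <- setdiff(c(measurement_key_cols, "value"), names(x))
  if (length(missing_cols)) {
    abort_rfd(sprintf("measurement table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "rfdtools_invalid_table")
  }
  out <- tibble::as_tibble(x)
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(measurement_key_cols),
                                          as.character))
  out$value <- as.double(out$value)
  if (any(is.infinite(out$value))) {
    abort_rfd("measurement values must be finite or NA", "rfdtools_invalid_table")
  }
  if (check_muscles) {
    bad <- setdiff(unique(out$muscle), muscle_codes())
    if (length(bad)) {
      abort_rfd(sprintf("unknown muscle code(s): %s", paste(bad, collapse = ", ")),
                "rfdtools_invalid_table")
    }
  }
  dup <- dplyr::filter(dplyr::count(out, !!!rlang::syms(measurement_key_cols)),
                       .data$n > 1)
  if (nrow(dup)) {
    first <- dup[1, measurement_key_cols]
    abort_rfd(sprintf("duplicate key tuple(s), e.g. (%s)",
                      paste(unlist(first), collapse = ", ")),
              "rfdtools_duplicate_key")
  }
  class(out) <- c("measurement_table", class(tibble::tibble()))
  out
}

#' @rdname as_measurement_table
#' @param path CSV path with header `participant,muscle,device,rater,session,metric,value`.
#' @export
read_measurements <- function(path, check_muscles = TRUE) {
  if (!file.exists(path)) {
    abort_rfd(sprintf("measurement file not found: %s", path), "rfdtools_io_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()
                         ))
  # base R strtod is correctly rounded, so the %.17g round trip is exact
  dat$value <- as.numeric(dat$value)
  as_measurement_table(dat, check_muscles = check_muscles)
}

#' @rdname as_measurement_table
#' @param table A `measurement_table`.
#' @export
write_measurements <- function(table, path) {
  table <- as_measurement_table(table, check_muscles = FALSE)
  out <- table[, c(measurement_key_cols, "value")]
  # %.17g guarantees the written decimal parses back to the same double
  out$value <- ifelse(is.na(out$value), NA_character_,
                      sprintf("%.17g", out$value))
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}
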