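#' Read and write designs and time series
#'
#' Designs travel as CSV (a single `time` column, unit-interval floats) or
#' JSON (`times`, `n`, optional `time_unit` and `study_length`). Series are
#' CSV with `time` and `value` columns. Times in clock units are normalized
#' to the unit interval on read when `study_length` is present; raw times
#' outside `[0, 1)` without a `study_length` are an error. Round trips are
#' lossless at full double precision.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return `read_design()` returns a [design()]; `read_series()` a tibble
#'   with `time` and `value`.
#' @export
read_design <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    times <- as.numeric(obj$times)
    if (!is.null(obj$study_length) && obj$study_length != 1) {
      times <- times / obj$study_length
    }
    check_unit_times(times, path)
    d <- design(times)
    attr(d, "time_unit") <- obj$time_unit
    attr(d, "study_length") <- obj$study_length
    d
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"time" %in% names(df)) {
      rlang::abort(sprintf("%s: missing required column 'time'", path),
        class = "rhythmdesign_error_io")
    }
    check_unit_times(df$time, path)
    design(df$time)
  }
}

check_unit_times <- function(times, path) {
  bad <- which(times < 0 | times >= 1)
  if (length(bad)) {
    rlang::abort(
      sprintf("%s: time outside [0, 1) at row %d; supply a study_length to normalize",
              path, bad[1]),
      class = "rhythmdesign_error_io")
  }
  invisible(times)
}

#' @rdname read_design
#' @param d A [design()].
#' @param time_unit,study_length Optional metadata for JSON output: times are
#'   written in clock units (`unit-interval time * study_length`) and
#'   re-normalized on read, so round trips are lossless.
#' @export
write_design <- function(d, path, time_unit = "interval", study_length = 1) {
  d <- as_design(d)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(times = as.numeric(d) * study_length, n = attr(d, "n"),
           time_unit = time_unit, study_length = study_length),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(tibble::tibble(time = as.numeric(d)), path)
  }
  invisible(path)
}

#' @rdname read_design
#' @export
read_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "value") %in% names(df))) {
    rlang::abort(sprintf("%s: need columns 'time' and 'value'", path),
      class = "rhythmdesign_error_io")
  }
  check_unit_times(df$time, path)
  tibble::as_tibble(df[order(df$time), c("time", "value")])
}

#' @rdname read_design
#' @param series Tibble with `time` and `value` columns.
#' @export
write_series <- function(series, path) {
  readr::write_csv(series[, c("time", "value")], path)
  invisible(path)
}
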