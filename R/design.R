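#' Measurement designs on the unit study interval
#'
#' A design is an ordered set of measurement times expressed as fractions of
#' the study interval, so every time lies in `[0, 1)`. Frequencies are then
#' cycles per study interval (a 24 h study probed for a 2 h rhythm uses
#' `frequency = 12`). All power and optimization functions in the package
#' consume and produce these objects.
#'
#' @param times Numeric vector of measurement times. Values must lie in
#'   `[0, 1)`; they are sorted on construction.
#' @param allow_duplicates If `FALSE` (default), duplicated raw times are an
#'   error: at most one measurement per linear time. Phases may still
#'   coincide modulo a shorter period.
#' @return An object of class `rhythm_design`: a sorted numeric vector of
#'   times with attribute `n`.
#' @examples
#' design(c(0, 0.25, 0.5, 0.75))
#' design_equispaced(8)
#' @export
design <- function(times, allow_duplicates = FALSE) {
  times <- as.numeric(times)
  if (length(times) < 1L) {
    rlang::abort("a design needs at least one measurement time",
      class = "rhythmdesign_error_design")
  }
  if (anyNA(times)) {
    rlang::abort("measurement times must not contain NA",
      class = "rhythmdesign_error_design")
  }
  if (any(times < 0 | times >= 1)) {
    rlang::abort(
      "measurement times must lie in [0, 1); normalize by the study length first",
      class = "rhythmdesign_error_design")
  }
  times <- sort(times)
  if (!allow_duplicates && anyDuplicated(times)) {
    rlang::abort("duplicated measurement times (at most one measurement per linear time)",
      class = "rhythmdesign_error_design")
  }
  structure(times, n = length(times), class = "rhythm_design")
}

#' @rdname design
#' @param x Object to coerce or test.
#' @export
as_design <- function(x) {
  if (inherits(x, "rhythm_design")) x else design(x)
}

#' @rdname design
#' @export
is_design <- function(x) inherits(x, "rhythm_design")

#' @rdname design
#' @param n Number of measurements.
#' @param offset Common rotation added to all times (modulo 1).
#' @export
design_equispaced <- function(n, offset = 0) {
  design(((seq_len(n) - 1) / n + offset) %% 1)
}

#' Build a design from a binary occupancy mask on a uniform partition
#'
#' Grid designs encode measurements as a binary vector over the partition
#' `{k/n_t : 0 <= k < n_t}`; slot `k` (1-based index `k + 1`) corresponds to
#' time `k / n_t`.
#'
#' @param mask Binary (0/1 or logical) vector of length `n_t`.
#' @param n_t Partition coarseness; defaults to `length(mask)`.
#' @return A [design()].
#' @export
design_from_mask <- function(mask, n_t = length(mask)) {
  mask <- as.logical(mask)
  if (length(mask) != n_t) {
    rlang::abort("mask length must equal n_t", class = "rhythmdesign_error_design")
  }
  design((which(mask) - 1) / n_t)
}

#' @rdname design_from_mask
#' @param d A design whose times all sit on the partition.
#' @export
design_to_mask <- function(d, n_t) {
  d <- as_design(d)
  slots <- round(as.numeric(d) * n_t)
  if (max(abs(as.numeric(d) * n_t - slots)) > 1e-9 || anyDuplicated(slots)) {
    rlang::abort("design times do not sit on the n_t-slot partition",
      class = "rhythmdesign_error_design")
  }
  mask <- integer(n_t)
  mask[slots + 1L] <- 1L
  mask
}

#' Nyquist rate of an equispaced design
#'
#' For `n` equispaced measurements on the unit interval the Nyquist rate is
#' `n / 2` cycles per interval; frequencies at (and near) it are blindspots
#' of equispaced sampling.
#'
#' @param n Sample size, or a design (its size is used).
#' @return `n / 2`.
#' @export
nyquist_rate <- function(n) {
  if (is_design(n)) n <- attr(n, "n")
  n / 2
}

#' @export
print.rhythm_design <- function(x, ...) {
  cat(sprintf("<rhythm_design> %d measurement times on [0, 1)\n", attr(x, "n")))
  print(as.numeric(x), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rhythm_design <- function(x, study_length = 1, ...) {
  tibble::tibble(
    index = seq_len(attr(x, "n")),
    time = as.numeric(x) * study_length
  )
}
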