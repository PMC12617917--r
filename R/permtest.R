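#' Frequency window for free-period analysis
#'
#' A uniform grid of `n_grid` frequencies on `[f_min, f_max]`. When paired
#' with a design, grid frequencies at which the design matrix is numerically
#' singular (e.g. an equispaced design at its Nyquist rate) are excluded
#' from the amplitude profile; the exclusions are recorded.
#'
#' @param f_min,f_max Window bounds, `0 < f_min < f_max`.
#' @param n_grid Number of grid frequencies (`>= 2`).
#' @return A `freq_window` list with `f_min`, `f_max`, `frequencies`.
#' @export
freq_window <- function(f_min, f_max, n_grid = 48) {
  if (!(f_min > 0 && f_max > f_min)) rlang::abort("need 0 < f_min < f_max")
  if (n_grid < 2) rlang::abort("n_grid must be >= 2")
  structure(
    list(f_min = f_min, f_max = f_max,
         frequencies = seq(f_min, f_max, length.out = n_grid)),
    class = "freq_window"
  )
}

# linear operator extracting (beta1, beta2) at every retained grid frequency:
# a list with `frequencies` (retained), `excluded`, and `B` (2G x N matrix);
# amplitudes of any response matrix Y are sqrt(B1 Y)^2 + (B2 Y)^2 row-pairs
profile_operator <- function(d, window) {
  d <- as_design(d)
  keep <- logical(length(window$frequencies))
  rows <- vector("list", length(window$frequencies))
  for (i in seq_along(window$frequencies)) {
    f <- window$frequencies[i]
    X <- design_matrix(d, f)
    xtx <- crossprod(X)
    if (is_singular_xtx(xtx)) next
    keep[i] <- TRUE
    rows[[i]] <- solve(xtx, t(X))[2:3, , drop = FALSE]
  }
  if (!any(keep)) {
    rlang::abort("design is singular at every window frequency",
      class = "rhythmdesign_error_singular")
  }
  list(
    frequencies = window$frequencies[keep],
    excluded = window$frequencies[!keep],
    B = do.call(rbind, rows[keep])
  )
}

# amplitude profiles for response matrix Y (N x m): returns G x m matrix
profile_amplitudes <- function(op, Y) {
  BY <- op$B %*% Y
  G <- length(op$frequencies)
  b1 <- BY[2 * seq_len(G) - 1, , drop = FALSE]
  b2 <- BY[2 * seq_len(G), , drop = FALSE]
  sqrt(b1^2 + b2^2)
}

#' Amplitude profile of a series over a frequency window
#'
#' Per-frequency least-squares amplitude estimates `A_f = |(b1, b2)|` of the
#' fixed-period cosinor fit at each retained grid frequency.
#'
#' @param y Response vector (one value per design time).
#' @param d A [design()].
#' @param window A [freq_window()].
#' @return A tibble with `frequency` and `amplitude`; excluded (singular)
#'   frequencies are recorded in attribute `excluded`.
#' @export
amplitude_profile <- function(y, d, window) {
  op <- profile_operator(d, window)
  amp <- drop(profile_amplitudes(op, matrix(y, ncol = 1)))
  out <- tibble::tibble(frequency = op$frequencies, amplitude = amp)
  attr(out, "excluded") <- op$excluded
  out
}

#' Amplitude test statistics for free-period rhythm detection
#'
#' `stat_t2` integrates the squared amplitude profile over the frequency
#' window (trapezoidal rule on the retained grid); `stat_tinf` takes the
#' profile's maximum. Both depend on the data only through the amplitude
#' profile and are permutation-invariant under the exchangeable null.
#'
#' @inheritParams amplitude_profile
#' @return Scalar statistic.
#' @export
stat_t2 <- function(y, d, window) {
  prof <- amplitude_profile(y, d, window)
  trapezoid(prof$frequency, prof$amplitude^2)
}

#' @rdname stat_t2
#' @export
stat_tinf <- function(y, d, window) {
  prof <- amplitude_profile(y, d, window)
  max(prof$amplitude)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# statistics for a matrix of responses, computed once through the operator
stats_matrix <- function(op, Y) {
  A <- profile_amplitudes(op, Y)
  f <- op$frequencies
  t2 <- if (length(f) > 1) {
    w <- diff(f)
    colSums(A^2 * c(w / 2, 0) + A^2 * c(0, w / 2))
  } else {
    rep(0, ncol(A))
  }
  list(t2 = t2, tinf = apply(A, 2, max))
}

#' Permutation test of rhythmicity with free-period amplitude statistics
#'
#' Permutes the response against the fixed measurement times and reports the
#' achieved significance of the chosen amplitude statistic. The Monte-Carlo
#' estimator uses `n_perm` uniformly random permutations with add-one
#' smoothing, `p = (1 + #\{T(perm) >= T(obs)\}) / (n_perm + 1)`, which is a
#' valid p-value and never zero. For `N <= 7`, `exact = TRUE` averages the
#' strict-inequality indicator over all `N!` permutations instead.
#'
#' @inheritParams amplitude_profile
#' @param statistic `"tinf"` (peak amplitude) or `"t2"` (integrated squared
#'   amplitude).
#' @param n_perm Number of random permutations (`>= 20`).
#' @param exact Enumerate all permutations (requires `length(y) <= 7`).
#' @param seed Optional integer seed.
#' @return A `perm_test_result` with `statistic`, `p_value`, `n_perm`,
#'   `statistic_kind`.
#' @export
perm_test <- function(y, d, window, statistic = c("tinf", "t2"),
                      n_perm = 999, exact = FALSE, seed = NULL) {
  statistic <- rlang::arg_match(statistic)
  d <- as_design(d)
  n <- attr(d, "n")
  if (length(y) != n) rlang::abort("length(y) must match the design")
  op <- profile_operator(d, window)
  obs <- stats_matrix(op, matrix(y, ncol = 1))[[statistic]]
  if (exact) {
    if (n > 7) rlang::abort("exact enumeration supported only for N <= 7")
    perms <- all_permutations(n)
    Yp <- matrix(y[perms], nrow = n)
    tp <- stats_matrix(op, Yp)[[statistic]]
    p <- mean(tp > obs + 1e-12)
    n_used <- ncol(perms)
  } else {
    if (n_perm < 20) rlang::abort("n_perm must be >= 20")
    Yp <- with_seed_opt(seed, {
      matrix(y[replicate(n_perm, sample.int(n))], nrow = n)
    })
    tp <- stats_matrix(op, Yp)[[statistic]]
    p <- (1 + sum(tp >= obs)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(statistic = unname(obs), p_value = p, n_perm = n_used,
         statistic_kind = statistic, excluded = op$excluded),
    class = "perm_test_result"
  )
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(i) {
    rbind(i, ifelse(sub >= i, sub + 1L, sub) * 1L)
  }))
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("<perm_test_result> %s = %.5g  p = %.5g  (%d permutations)\n",
              x$statistic_kind, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
glance.perm_test_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    n_perm = x$n_perm, statistic_kind = x$statistic_kind
  )
}

#' Permutation-test power of a design across frequencies and acrophases
#'
#' Simulates cosinor signals at every combination of the supplied
#' frequencies and acrophases, estimates the rejection rate of the
#' permutation test at level `alpha` from `n_samp` independent datasets per
#' cell (each tested with `n_perm` permutations), and reports the minimum
#' power over acrophase per frequency.
#'
#' @param d A [design()].
#' @param frequencies Signal frequencies to probe.
#' @param n_acro Number of acrophases on a uniform grid of `[0, 2*pi)`.
#' @param amplitude,sigma Signal parameters.
#' @param alpha Test level.
#' @param n_samp Simulated datasets per cell.
#' @param n_perm Permutations per dataset.
#' @param window A [freq_window()] for the test statistic.
#' @param statistic `"tinf"` or `"t2"`.
#' @param seed Integer seed.
#' @return A tibble with `frequency` and `min_power`; the full
#'   frequency-by-acrophase power table is in attribute `cells`.
#' @export
perm_power <- function(d, frequencies, n_acro = 8, amplitude = 1, sigma = 1,
                       alpha = 0.05, n_samp = 100, n_perm = 100,
                       window, statistic = c("tinf", "t2"), seed) {
  statistic <- rlang::arg_match(statistic)
  d <- as_design(d)
  n <- attr(d, "n")
  op <- profile_operator(d, window)
  acros <- 2 * pi * (seq_len(n_acro) - 1) / n_acro
  t <- as.numeric(d)
  cells <- with_seed_opt(seed, {
    grid <- tidyr::expand_grid(frequency = frequencies, acrophase = acros)
    grid$power <- purrr::pmap_dbl(grid, function(frequency, acrophase) {
      mu <- amplitude * cos(2 * pi * frequency * t - acrophase)
      rej <- purrr::map_lgl(seq_len(n_samp), function(s) {
        y <- mu + sigma * stats::rnorm(n)
        Y <- cbind(y, matrix(y[replicate(n_perm, sample.int(n))], nrow = n))
        st <- stats_matrix(op, Y)[[statistic]]
        p <- (1 + sum(st[-1] >= st[1])) / (n_perm + 1)
        p <= alpha
      })
      mean(rej)
    })
    grid
  })
  out <- cells |>
    dplyr::group_by(.data$frequency) |>
    dplyr::summarise(min_power = min(.data$power), .groups = "drop")
  attr(out, "cells") <- cells
  out
}

#' Area under the ROC curve from two score samples
#'
#' Rank-sum (Mann-Whitney) estimator: the probability that a positive score
#' outranks a negative one, counting ties as one half.
#'
#' @param scores_positive,scores_negative Numeric score vectors; both must
#'   be non-empty.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores_positive, scores_negative) {
  np <- length(scores_positive)
  nn <- length(scores_negative)
  if (np == 0 || nn == 0) {
    rlang::abort("both score groups must be non-empty",
      class = "rhythmdesign_error_domain")
  }
  r <- rank(c(scores_positive, scores_negative))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
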