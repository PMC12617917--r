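#' Noncentrality parameter of the cosinor F-test
#'
#' For the rhythm-detection F-test (null: both trigonometric coefficients
#' zero) at arbitrary measurement times, the noncentral-F shift parameter is
#' `lambda = b' (H (X'X)^-1 H')^-1 b / sigma^2`, where `b = (beta1, beta2)`
#' are the trigonometric coefficients implied by amplitude and acrophase and
#' `H` selects them.
#'
#' @param d A [design()] with more than 3 measurements.
#' @param params A [cosinor_params()].
#' @return Nonnegative scalar `lambda`.
#' @export
noncentrality <- function(d, params) {
  d <- as_design(d)
  if (attr(d, "n") <= 3) {
    rlang::abort("power analysis requires N > 3", class = "rhythmdesign_error_design")
  }
  if (params$sigma <= 0) rlang::abort("sigma must be > 0 for power analysis")
  X <- design_matrix(d, params$frequency)
  xtx <- crossprod(X)
  if (is_singular_xtx(xtx)) abort_singular(params$frequency)
  b <- params_to_beta(params)[2:3]
  binv <- solve(xtx)[2:3, 2:3] # H (X'X)^-1 H'
  drop(crossprod(b, solve(binv, b))) / params$sigma^2
}

# power of the noncentral-F test at a given lambda
power_from_lambda <- function(lambda, n, alpha) {
  crit <- stats::qf(1 - alpha, 2, n - 3)
  1 - stats::pf(crit, 2, n - 3, ncp = lambda)
}

#' Exact power of the fixed-period cosinor F-test
#'
#' Closed-form power at arbitrary measurement times: the survival function of
#' the noncentral F distribution with `(2, N - 3)` degrees of freedom and
#' noncentrality [noncentrality()] evaluated at the level-`alpha` central-F
#' critical value. Equals `alpha` when the amplitude is zero and increases
#' strictly with the noncentrality parameter.
#'
#' @inheritParams noncentrality
#' @param alpha Type-I error rate in `(0, 1)`.
#' @return Power in `(0, 1)`.
#' @export
power_fixed <- function(d, params, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) rlang::abort("alpha must be in (0, 1)")
  d <- as_design(d)
  lam <- noncentrality(d, params)
  power_from_lambda(lam, attr(d, "n"), alpha)
}

#' Worst-case-acrophase information matrix of a design
#'
#' Returns `B(t; f)^-1 = Xt'Xt - b b'/N`, where `Xt` is the trigonometric
#' block (cosine and sine columns) of the design matrix and `b` its column
#' sums. This equals the inverse of `H (X'X)^-1 H'` whenever `X'X` is
#' invertible, but is defined (and positive semidefinite) for every design;
#' degenerate designs yield a zero eigenvalue.
#'
#' @param d A [design()].
#' @param frequency Frequency in cycles per study interval.
#' @return Symmetric 2 x 2 matrix.
#' @export
b_inverse <- function(d, frequency) {
  d <- as_design(d)
  t <- as.numeric(d)
  n <- length(t)
  cv <- cos(2 * pi * frequency * t)
  sv <- sin(2 * pi * frequency * t)
  b <- c(sum(cv), sum(sv))
  m <- rbind(
    c(sum(cv * cv), sum(cv * sv)),
    c(sum(cv * sv), sum(sv * sv))
  )
  m - tcrossprod(b) / n
}

#' Minimum-eigenvalue (worst-case acrophase) design criterion
#'
#' The smallest eigenvalue of [b_inverse()], computed in closed form for the
#' 2 x 2 case. It determines the lowest noncentrality parameter over all
#' acrophases via `lambda_min = (A^2 / sigma^2) * xi_min`, and is bounded by
#' `N / 2`, attained by equispaced designs at any integer frequency below
#' the Nyquist rate. Degenerate (singular) designs return 0 rather than an
#' error so optimizers can score them continuously.
#'
#' @inheritParams b_inverse
#' @return Scalar in `[0, N/2]` (up to roundoff; tiny negatives are clipped).
#' @export
worstcase_eigenvalue <- function(d, frequency) {
  m <- b_inverse(d, frequency)
  max(0, eig_min_2x2(m[1, 1], m[1, 2], m[2, 2]))
}

#' Worst-case objective over a set of frequencies
#'
#' Scores a design for discrete period uncertainty by
#' `J(t) = min over f in F of xi_min(B(t; f)^-1)`, and converts the result
#' to the worst-case noncentrality `lambda = (A^2/sigma^2) J` and worst-case
#' power at level `alpha`.
#'
#' @param d A [design()].
#' @param frequencies Non-empty numeric vector of frequencies of interest.
#' @param amplitude,sigma Signal amplitude and noise SD used for the power
#'   conversion (the maximizing design does not depend on them).
#' @param alpha Type-I error rate for the power conversion.
#' @return An `objective_report` with `per_frequency` (tibble of `frequency`,
#'   `xi_min`, `lambda`, `worst_power`), `j_value`, `worst_case_lambda` and
#'   `worst_case_power`. [tidy()] returns the per-frequency tibble, [glance()]
#'   the scalar summary.
#' @export
multifreq_objective <- function(d, frequencies, amplitude = 1, sigma = 1,
                                alpha = 0.05) {
  if (length(frequencies) < 1) rlang::abort("need at least one frequency")
  d <- as_design(d)
  n <- attr(d, "n")
  xi <- purrr::map_dbl(frequencies, ~ worstcase_eigenvalue(d, .x))
  lam <- (amplitude^2 / sigma^2) * xi
  pw <- if (n > 3) power_from_lambda(lam, n, alpha) else rep(NA_real_, length(xi))
  per <- tibble::tibble(
    frequency = as.numeric(frequencies),
    xi_min = xi, lambda = lam, worst_power = pw
  )
  j <- min(xi)
  structure(
    list(
      per_frequency = per,
      j_value = j,
      worst_case_lambda = (amplitude^2 / sigma^2) * j,
      worst_case_power = if (n > 3) power_from_lambda((amplitude^2 / sigma^2) * j, n, alpha) else NA_real_,
      n = n, amplitude = amplitude, sigma = sigma, alpha = alpha
    ),
    class = "objective_report"
  )
}

#' @export
print.objective_report <- function(x, ...) {
  cat(sprintf(
    "<objective_report> J = %.6g  (worst-case lambda %.6g, worst-case power %.4g)\n",
    x$j_value, x$worst_case_lambda, x$worst_case_power
  ))
  print(x$per_frequency, ...)
  invisible(x)
}

#' @export
tidy.objective_report <- function(x, ...) x$per_frequency

#' @export
glance.objective_report <- function(x, ...) {
  tibble::tibble(
    j_value = x$j_value,
    worst_case_lambda = x$worst_case_lambda,
    worst_case_power = x$worst_case_power,
    n = x$n, amplitude = x$amplitude, sigma = x$sigma, alpha = x$alpha
  )
}

#' Power as a function of acrophase, and its peak-to-trough variability
#'
#' Scans the acrophase on a uniform grid of `[0, 2*pi)`, evaluating the exact
#' fixed-period power at each phase. The summary `delta` (max minus min, in
#' percentage points of power) quantifies how unevenly a design detects
#' rhythms of different peak times; equispaced designs have `delta = 0`. The
#' reported `min_power_eigen` is the exact worst case computed through the
#' minimum-eigenvalue route rather than the grid.
#'
#' @inheritParams b_inverse
#' @param amplitude,sigma Signal amplitude and noise SD.
#' @param alpha Type-I error rate.
#' @param n_phase Number of acrophase grid points (`>= 8`).
#' @return An `acrophase_scan` with `min_power`, `max_power`, `delta`
#'   (percentage points), `min_power_eigen`, and `curve` (tibble of
#'   `acrophase`, `power`).
#' @export
worstcase_power_acrophase <- function(d, frequency, amplitude, sigma = 1,
                                      alpha = 0.05, n_phase = 256) {
  if (n_phase < 8) rlang::abort("n_phase must be >= 8")
  d <- as_design(d)
  n <- attr(d, "n")
  phis <- 2 * pi * (seq_len(n_phase) - 1) / n_phase
  # lambda(phi) = b(phi)' Binv b(phi) / sigma^2 with b = A (cos phi, sin phi)
  m <- b_inverse(d, frequency)
  if (eig_min_2x2(m[1, 1], m[1, 2], m[2, 2]) <= .Machine$double.eps * n) {
    # exact power undefined at a singular frequency
    abort_singular(frequency)
  }
  bc <- amplitude * cos(phis)
  bs <- amplitude * sin(phis)
  lam <- (m[1, 1] * bc^2 + 2 * m[1, 2] * bc * bs + m[2, 2] * bs^2) / sigma^2
  pw <- power_from_lambda(lam, n, alpha)
  xi <- worstcase_eigenvalue(d, frequency)
  structure(
    list(
      frequency = frequency,
      min_power = min(pw), max_power = max(pw),
      delta = 100 * (max(pw) - min(pw)),
      min_power_eigen = power_from_lambda((amplitude^2 / sigma^2) * xi, n, alpha),
      curve = tibble::tibble(acrophase = phis, power = pw)
    ),
    class = "acrophase_scan"
  )
}

#' @export
print.acrophase_scan <- function(x, ...) {
  cat(sprintf(
    "<acrophase_scan> f=%g  power range [%.4f, %.4f]  delta = %.4g pp\n",
    x$frequency, x$min_power, x$max_power, x$delta
  ))
  invisible(x)
}

#' @export
tidy.acrophase_scan <- function(x, ...) x$curve

#' @export
glance.acrophase_scan <- function(x, ...) {
  tibble::tibble(
    frequency = x$frequency, min_power = x$min_power,
    max_power = x$max_power, delta = x$delta,
    min_power_eigen = x$min_power_eigen
  )
}

#' Monte-Carlo estimate of cosinor F-test power
#'
#' Simulation oracle for [power_fixed()]: simulates cosinor datasets at the
#' design times, applies the F-test at level `alpha`, and reports the
#' rejection fraction with its binomial standard error.
#'
#' @inheritParams power_fixed
#' @param n_sim Number of simulated datasets (`>= 100`).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `estimate`, `se`, `n_sim`.
#' @export
monte_carlo_power <- function(d, params, alpha = 0.05, n_sim = 10000, seed = NULL) {
  if (n_sim < 100) rlang::abort("n_sim must be >= 100")
  d <- as_design(d)
  n <- attr(d, "n")
  if (n <= 3) rlang::abort("power analysis requires N > 3",
    class = "rhythmdesign_error_design")
  X <- design_matrix(d, params$frequency)
  xtx <- crossprod(X)
  if (is_singular_xtx(xtx)) abort_singular(params$frequency)
  mu <- params$mesor + params$amplitude *
    cos(2 * pi * params$frequency * as.numeric(d) - params$acrophase)
  hat <- X %*% solve(xtx, t(X)) # projection onto the model space
  crit <- stats::qf(1 - alpha, 2, n - 3)
  rej <- with_seed_opt(seed, {
    Y <- mu + params$sigma * matrix(stats::rnorm(n * n_sim), n, n_sim)
    fitted <- hat %*% Y
    rss <- colSums((Y - fitted)^2)
    tss <- colSums((Y - rep(colMeans(Y), each = n))^2)
    fstat <- ((tss - rss) / 2) / (rss / (n - 3))
    mean(fstat >= crit)
  })
  tibble::tibble(
    estimate = rej,
    se = sqrt(rej * (1 - rej) / n_sim),
    n_sim = n_sim
  )
}
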