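#' Build a mixed-integer conic instance for multi-frequency design optimization
#'
#' Precomputes, for each frequency, the per-slot cosinor regressor rows
#' `x_k = (1, cos(2*pi*f*k/n_t), sin(2*pi*f*k/n_t))` on the uniform
#' partition, so that the lifted information matrix
#' `X' diag(mu) X = sum over selected slots of x_k x_k'` is linear in the
#' occupancy mask `mu`. The program maximizes `eta` subject to
#' `X' diag(mu) X - eta I` positive semidefinite at every frequency, with
#' exactly `n` slots selected; `eta` is bounded above by `n/2`.
#'
#' @param n Sample budget (number of selected slots).
#' @param n_t Partition coarseness.
#' @param frequencies Frequencies of interest.
#' @return A `micp_instance`.
#' @export
micp_instance <- function(n, n_t, frequencies) {
  n <- as.integer(n); n_t <- as.integer(n_t)
  if (n > n_t) rlang::abort("infeasible: n > n_t", class = "rhythmdesign_error_infeasible")
  if (length(frequencies) < 1) rlang::abort("need at least one frequency")
  slots <- (0:(n_t - 1)) / n_t
  X <- purrr::map(frequencies, function(f) {
    cbind(1, cos(2 * pi * f * slots), sin(2 * pi * f * slots))
  })
  structure(
    list(n = n, n_t = n_t, frequencies = as.numeric(frequencies), X = X),
    class = "micp_instance"
  )
}

# X' diag(mu) X for frequency index fi and logical/0-1 mask
lifted_matrix <- function(instance, mask, fi) {
  Xs <- instance$X[[fi]][as.logical(mask), , drop = FALSE]
  crossprod(Xs)
}

#' Check a positive-semidefiniteness certificate for a mask
#'
#' `TRUE` iff, at every frequency of the instance, the smallest eigenvalue
#' of `X' diag(mu) X - eta I` is at least `-tol`.
#'
#' @param mask Binary vector of length `n_t` with `sum(mask) == n`.
#' @param eta Candidate objective value.
#' @param instance A [micp_instance()].
#' @param tol Eigenvalue tolerance.
#' @return Logical.
#' @export
verify_certificate <- function(mask, eta, instance, tol = 1e-6) {
  stopifnot(inherits(instance, "micp_instance"))
  if (sum(mask) != instance$n) {
    rlang::abort("mask must select exactly n slots")
  }
  for (fi in seq_along(instance$frequencies)) {
    ev <- eigen(lifted_matrix(instance, mask, fi), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) - eta < -tol) return(FALSE)
  }
  TRUE
}

#' Solve the design program by eigenvector cutting planes
#'
#' Outer approximation of the semidefinite constraints: the master problem
#' keeps a set of linear cuts `sum_k mu_k (v' x_k)^2 >= eta` (one per unit
#' vector `v` and frequency) and maximizes `eta` over fixed-cardinality
#' binary masks; at the incumbent, each frequency's lifted matrix is
#' eigen-decomposed and any eigenvector violating `eta` by more than `tol`
#' is added as a new cut. At termination with no violated cut the incumbent
#' is optimal for the conic program and carries a PSD certificate
#' ([verify_certificate()]). The master problem is solved exactly by
#' vectorized enumeration of the feasible masks (cut values are min-folded
#' incrementally, so each iteration only scores the new cuts), which bounds
#' the instance sizes this solver accepts.
#'
#' @param instance A [micp_instance()].
#' @param max_iter Maximum number of cutting-plane iterations.
#' @param tol Eigenvalue violation tolerance.
#' @param mask_cap Maximum number of feasible masks the enumeration master
#'   will accept.
#' @return A `micp_result`: `mask`, `design`, `eta` (certified objective),
#'   `eta_relaxation` (master upper bound), `gap`, `status` (`"optimal"` or
#'   `"iteration_limit"`), `n_cuts`, `n_iter`.
#' @export
solve_micp <- function(instance, max_iter = 200, tol = 1e-6, mask_cap = 3e5) {
  stopifnot(inherits(instance, "micp_instance"))
  n <- instance$n; n_t <- instance$n_t
  total <- choose(n_t, n)
  if (total > mask_cap) {
    rlang::abort(sprintf(
      "master enumeration over %g masks exceeds mask_cap %g", total, mask_cap),
      class = "rhythmdesign_error_cap")
  }
  combos <- comb_unrank(0:(total - 1), n_t, n) # n x total slot indices
  mincut <- rep(Inf, total) # running min over all cuts of the cut value
  n_cuts <- 0L
  add_cut <- function(fi, v) {
    coefs <- drop(instance$X[[fi]] %*% v)^2 # per-slot contribution (v' x_k)^2
    vals <- colSums(matrix(coefs[combos], n))
    mincut <<- pmin(mincut, vals)
    n_cuts <<- n_cuts + 1L
  }
  # initial cuts: coordinate unit vectors per frequency bound eta immediately
  for (fi in seq_along(instance$frequencies)) {
    for (j in 1:3) add_cut(fi, diag(3)[, j])
  }
  status <- "iteration_limit"
  eta_hat <- NA_real_
  best_idx <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- which.max(mincut)
    eta_hat <- min(mincut[w], n / 2) # Corollary bound eta <= n/2
    best_idx <- combos[, w]
    # separation: eigen-decompose each frequency's lifted matrix at incumbent
    violated <- FALSE
    for (fi in seq_along(instance$frequencies)) {
      Xs <- instance$X[[fi]][best_idx, , drop = FALSE]
      es <- eigen(crossprod(Xs), symmetric = TRUE)
      if (min(es$values) < eta_hat - tol) {
        add_cut(fi, es$vectors[, which.min(es$values)])
        violated <- TRUE
      }
    }
    if (!violated) {
      status <- "optimal"
      break
    }
  }
  mask <- integer(n_t)
  mask[best_idx] <- 1L
  feas <- feasible_value(instance, best_idx)
  structure(
    list(
      mask = mask,
      design = design_from_mask(mask, n_t),
      eta = feas,
      eta_relaxation = eta_hat,
      gap = max(0, eta_hat - feas),
      status = status,
      n_cuts = n_cuts,
      n_iter = iter
    ),
    class = "micp_result"
  )
}

# min over frequencies of the smallest eigenvalue of X' diag(mu) X
feasible_value <- function(instance, idx) {
  vals <- purrr::map_dbl(seq_along(instance$frequencies), function(fi) {
    Xs <- instance$X[[fi]][idx, , drop = FALSE]
    min(eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values)
  })
  min(vals)
}

#' @export
print.micp_result <- function(x, ...) {
  cat(sprintf(
    "<micp_result> status=%s  eta=%.6g  gap=%.2g  cuts=%d  iterations=%d\n",
    x$status, x$eta, x$gap, x$n_cuts, x$n_iter
  ))
  invisible(x)
}

#' @export
glance.micp_result <- function(x, ...) {
  tibble::tibble(
    status = x$status, eta = x$eta, eta_relaxation = x$eta_relaxation,
    gap = x$gap, n_cuts = x$n_cuts, n_iter = x$n_iter
  )
}
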