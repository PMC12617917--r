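#' Differential evolution over measurement times
#'
#' Classic DE/rand/1/bin on the `n`-dimensional cube of measurement times:
#' the population is initialized uniformly on `[0, 1)`; each generation, a
#' candidate for member `i` is built coordinate-wise — with probability
#' `crossover` the coordinate mutates to `x_a + weight * (x_b - x_c)` using
#' three distinct other members, otherwise it is copied — and replaces the
#' member only if strictly better. Mutated coordinates are wrapped modulo 1
#' (times are phases of the study interval). The default objective is the
#' multi-frequency worst-case eigenvalue criterion `J`
#' ([multifreq_objective()]), evaluated in vectorized batches across the
#' population.
#'
#' @param n Number of measurement times per design.
#' @param frequencies Frequencies for the default objective; ignored when
#'   `objective` is supplied.
#' @param objective Optional function mapping a numeric time vector to a
#'   scalar to be maximized.
#' @param pop_size Population size (`>= 4`).
#' @param weight Differential weight in `[0, 1]`.
#' @param crossover Crossover probability in `(0, 1)`.
#' @param n_iter Number of generations (`>= 1`).
#' @param seed Integer seed (required: runs are reproducible by contract).
#' @return An `optimization_result` with the best terminal member, its
#'   objective, and the per-generation best-objective `trace`
#'   (non-decreasing).
#' @export
optimize_de <- function(n, frequencies = NULL, objective = NULL,
                        pop_size = 1000, weight = 0.05, crossover = 0.05,
                        n_iter = 100, seed) {
  if (pop_size < 4) rlang::abort("pop_size must be >= 4")
  if (weight < 0 || weight > 1) rlang::abort("weight must be in [0, 1]")
  if (crossover <= 0 || crossover >= 1) rlang::abort("crossover must be in (0, 1)")
  if (n_iter < 1) rlang::abort("n_iter must be >= 1")
  if (is.null(objective) && is.null(frequencies)) {
    rlang::abort("supply frequencies (default objective) or an objective function")
  }
  batch_eval <- if (is.null(objective)) {
    function(P) xi_min_times_batch(P, frequencies)
  } else {
    function(P) apply(P, 2, function(t) objective(sort(t)))
  }
  with_seed_opt(seed, {
    P <- matrix(stats::runif(n * pop_size), n, pop_size)
    scores <- batch_eval(P)
    trace <- numeric(n_iter)
    for (g in seq_len(n_iter)) {
      U <- matrix(stats::runif(n * pop_size), n, pop_size) < crossover
      # three distinct partners a, b, c != i per member
      abc <- vapply(seq_len(pop_size), function(i) {
        sample(seq_len(pop_size)[-i], 3L)
      }, integer(3))
      Y <- P
      mut <- (P[, abc[1, ], drop = FALSE] +
                weight * (P[, abc[2, ], drop = FALSE] - P[, abc[3, ], drop = FALSE])) %% 1
      Y[U] <- mut[U]
      ynew <- batch_eval(Y)
      better <- ynew > scores
      P[, better] <- Y[, better]
      scores[better] <- ynew[better]
      trace[g] <- max(scores)
    }
    best <- which.max(scores)
    d <- design(sort(P[, best]), allow_duplicates = TRUE)
    new_optimization_result(
      design = d, objective = scores[best], method = "differential_evolution",
      trace = trace, seed = seed,
      pop_size = pop_size, weight = weight, crossover = crossover,
      n_iter = n_iter, frequencies = frequencies
    )
  })
}

# vectorized multi-frequency J over a population: times matrix n x B
xi_min_times_batch <- function(P, frequencies) {
  k <- nrow(P)
  res <- NULL
  for (f in frequencies) {
    C1 <- cos(2 * pi * f * P)
    S1 <- sin(2 * pi * f * P)
    c1 <- colSums(C1); s1 <- colSums(S1)
    cc <- colSums(C1 * C1)
    ss <- k - cc
    cs <- colSums(C1 * S1)
    a <- cc - c1 * c1 / k
    dd <- ss - s1 * s1 / k
    b <- cs - c1 * s1 / k
    xi <- pmax(0, (a + dd) / 2 - sqrt(((a - dd) / 2)^2 + b^2))
    res <- if (is.null(res)) xi else pmin(res, xi)
  }
  res
}

#' Constrained stochastic search with anchored times and a minimum gap
#'
#' Maximizes a user-supplied design objective over ordered times subject to
#' the spread constraints used for continuous period uncertainty: the first
#' time is anchored at 0, the time of index `n/2 + 1` at 1/2, and
#' consecutive times are at least `epsilon_gap` apart. Candidates proposed
#' by an internal differential-evolution loop are repaired onto the
#' constraint set (sorting, exact anchors, forward/backward gap sweeps)
#' before scoring, so the returned design satisfies all constraints exactly.
#' The default objective is the fixed-period worst-case heuristic
#' `J = min over frequencies of xi_min`.
#'
#' @param n Even number of measurement times.
#' @param frequencies Frequencies for the default objective.
#' @param objective Optional function of a sorted time vector, maximized.
#' @param epsilon_gap Minimum spacing between consecutive times; must
#'   satisfy `epsilon_gap * n/2 < 1/2`.
#' @param pop_size,weight,crossover,n_iter DE hyperparameters.
#' @param seed Integer seed.
#' @return An `optimization_result` (method `"constrained_search"`).
#' @export
constrained_search <- function(n, frequencies = NULL, objective = NULL,
                               epsilon_gap = 1e-3,
                               pop_size = 100, weight = 0.5, crossover = 0.5,
                               n_iter = 100, seed) {
  if (n %% 2 != 0 || n < 4) rlang::abort("n must be even and >= 4")
  h <- n / 2
  if (epsilon_gap * h >= 0.5) {
    rlang::abort("infeasible: epsilon_gap too large for the anchored halves",
      class = "rhythmdesign_error_infeasible")
  }
  if (is.null(objective)) {
    if (is.null(frequencies)) rlang::abort("supply frequencies or an objective")
    objective <- function(t) multifreq_objective(design(t, allow_duplicates = TRUE),
                                                 frequencies)$j_value
  }
  repaired_objective <- function(t) objective(repair_anchored(t, n, epsilon_gap))
  res <- optimize_de(
    n = n, objective = repaired_objective,
    pop_size = pop_size, weight = weight, crossover = crossover,
    n_iter = n_iter, seed = seed
  )
  final <- repair_anchored(as.numeric(res$design), n, epsilon_gap)
  new_optimization_result(
    design = design(final), objective = objective(final),
    method = "constrained_search", trace = res$trace, seed = seed,
    epsilon_gap = epsilon_gap, anchors = c(0, 0.5)
  )
}

# sort, anchor t[1] = 0 and t[n/2 + 1] = 1/2, enforce min gaps within halves
repair_anchored <- function(t, n, eps) {
  h <- n / 2
  t <- sort(t %% 1)
  first <- t[seq_len(h)]
  second <- t[(h + 1):n]
  first <- repair_segment(first, 0, 0.5, eps)
  second <- repair_segment(second, 0.5, 1, eps)
  c(first, second)
}

# anchor segment start at lo, forward-sweep min gaps, backward-cap so the
# last point keeps an eps gap before hi (the next anchor or the interval end);
# feasible whenever eps * length(x) <= hi - lo
repair_segment <- function(x, lo, hi, eps) {
  m <- length(x)
  x <- sort(x)
  x[1] <- lo
  for (k in seq_len(m - 1) + 1) x[k] <- max(x[k], x[k - 1] + eps)
  x[m] <- min(x[m], hi - eps)
  for (k in rev(seq_len(m - 1))) x[k] <- min(x[k], x[k + 1] - eps)
  x[1] <- lo
  x
}

#' Perturb a design's measurement times with Gaussian jitter
#'
#' Adds independent Gaussian noise (SD expressed as a fraction of the study
#' interval) to every measurement time, wraps modulo the unit interval
#' (times are phases), and re-sorts.
#'
#' @param d A [design()].
#' @param noise_sd Jitter standard deviation, `>= 0`.
#' @param seed Optional integer seed.
#' @return A jittered [design()].
#' @export
jitter_design <- function(d, noise_sd, seed = NULL) {
  d <- as_design(d)
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  if (noise_sd == 0) return(d)
  t <- as.numeric(d)
  with_seed_opt(seed, {
    design(sort((t + stats::rnorm(length(t), sd = noise_sd)) %% 1),
           allow_duplicates = TRUE)
  })
}

#' Worst-case power of a design under increasing timing jitter
#'
#' For each jitter level, draws `n_rep` jittered replicates of the design
#' and summarizes the distribution of their worst-case power (minimum over
#' acrophase and the frequency set, from the eigenvalue criterion).
#'
#' @param d A [design()].
#' @param frequencies Frequencies of interest.
#' @param amplitude,sigma,alpha Power conversion parameters.
#' @param noise_grid Numeric vector of jitter SDs (fractions of the study
#'   interval).
#' @param n_rep Number of jittered replicates per level (`>= 10`).
#' @param seed Integer seed.
#' @return A tibble with one row per noise level: `noise_sd`, `median`,
#'   `q25`, `q75` of worst-case power, of class `jitter_curve`.
#' @export
jitter_robustness <- function(d, frequencies, amplitude = 1, sigma = 1,
                              alpha = 0.05, noise_grid, n_rep = 100, seed) {
  if (n_rep < 10) rlang::abort("n_rep must be >= 10")
  d <- as_design(d)
  base_power <- multifreq_objective(d, frequencies, amplitude, sigma, alpha)$worst_case_power
  rows <- with_seed_opt(seed, {
    purrr::map(noise_grid, function(ns) {
      pw <- purrr::map_dbl(seq_len(n_rep), function(r) {
        dj <- jitter_design(d, ns)
        multifreq_objective(dj, frequencies, amplitude, sigma, alpha)$worst_case_power
      })
      if (ns == 0) pw <- rep(base_power, n_rep) # no perturbation: exact value
      tibble::tibble(
        noise_sd = ns,
        median = stats::median(pw),
        q25 = stats::quantile(pw, 0.25, names = FALSE),
        q75 = stats::quantile(pw, 0.75, names = FALSE)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("jitter_curve", class(out))
  out
}
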