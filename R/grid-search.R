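#' Count fixed-density binary necklaces
#'
#' Number of equivalence classes of binary strings of length `n_t` with
#' exactly `n` ones, under cyclic rotation:
#' `C(n, n_t) = (1/n_t) * sum over j | gcd(n, n_t) of phi(j) * choose(n_t/j, n/j)`
#' with `phi` Euler's totient. Grid designs that are rotations of one
#' another have identical worst-case power, so one representative per
#' necklace suffices in exhaustive searches.
#'
#' @param n Number of ones (measurements), `1 <= n <= n_t`.
#' @param n_t String length (partition coarseness).
#' @return Exact count as a double (integer-valued).
#' @export
count_necklaces <- function(n, n_t) {
  n <- as.integer(n); n_t <- as.integer(n_t)
  if (n < 1 || n > n_t) {
    rlang::abort("need 1 <= n <= n_t", class = "rhythmdesign_error_domain")
  }
  g <- gcd_int(n, n_t)
  js <- divisors_of(g)
  sum(vapply(js, function(j) euler_phi(j) * choose(n_t / j, n / j), numeric(1))) / n_t
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

#' Enumerate fixed-density binary necklaces
#'
#' Generates one canonical representative (the lexicographically smallest
#' rotation) per rotation class, via the fixed-density variant of the
#' classic pre-necklace recursion (FKM): candidate strings are grown left to
#' right keeping track of the longest Lyndon prefix, and a completed string
#' of length `n_t` is a necklace representative when its period divides
#' `n_t`.
#'
#' @inheritParams count_necklaces
#' @return Integer matrix with `n_t` rows, one column per necklace mask.
#' @export
enumerate_necklaces <- function(n, n_t) {
  n <- as.integer(n); n_t <- as.integer(n_t)
  if (n < 1 || n > n_t) {
    rlang::abort("need 1 <= n <= n_t", class = "rhythmdesign_error_domain")
  }
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 0)
  a <- integer(n_t)
  gen <- function(t, p, ones) {
    if (ones > n || (n - ones) > (n_t - t + 1L)) return(invisible())
    if (t > n_t) {
      if (n_t %% p == 0L && ones == n) acc$out[[length(acc$out) + 1L]] <- a[seq_len(n_t)]
      return(invisible())
    }
    # FKM: a[t] ranges from a[t - p] upward (binary alphabet 0 < 1)
    lo <- a[t - p]
    if (lo == 0L) {
      a[t] <<- 0L
      gen(t + 1L, p, ones)
      a[t] <<- 1L
      gen(t + 1L, t, ones + 1L)
    } else {
      a[t] <<- 1L
      gen(t + 1L, p, ones + 1L)
    }
  }
  a[1] <- 0L
  if (n < n_t) gen(2L, 1L, 0L) # strings starting with 0
  # the all-ones prefix case: necklace of all ones only when n == n_t
  if (n == n_t) acc$out[[length(acc$out) + 1L]] <- rep(1L, n_t)
  masks <- do.call(cbind, acc$out)
  # FKM emits lexicographically largest-period representatives built from the
  # smallest-rotation convention with 0 < 1; normalize to lexicographically
  # smallest rotation explicitly for a stable public contract
  apply(masks, 2, canonical_rotation)
}

# lexicographically smallest rotation of a binary mask
canonical_rotation <- function(mask) {
  n_t <- length(mask)
  rots <- vapply(seq_len(n_t) - 1L, function(s) {
    paste(mask[((seq_len(n_t) - 1L + s) %% n_t) + 1L], collapse = "")
  }, character(1))
  best <- which.min(rots)
  s <- best - 1L
  mask[((seq_len(n_t) - 1L + s) %% n_t) + 1L]
}

# minimum xi over `frequencies` for a batch of masks given as a k x B matrix
# of 1-based slot indices on an n_t partition; returns length-B vector
xi_min_batch_slots <- function(idx, n_t, frequencies) {
  k <- nrow(idx)
  res <- NULL
  for (f in frequencies) {
    ang <- 2 * pi * f * (0:(n_t - 1)) / n_t
    cosv <- cos(ang); sinv <- sin(ang)
    C1 <- matrix(cosv[idx], k)
    S1 <- matrix(sinv[idx], k)
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

#' Exhaustive grid search for the worst-case-power-optimal design
#'
#' Maximizes the multi-frequency minimum-eigenvalue objective
#' ([multifreq_objective()]) over all placements of `n` measurements on an
#' `n_t`-slot uniform partition. Without timing constraints the search runs
#' over one representative per rotation class (fixed-density necklaces);
#' with an `allowed` mask (which breaks rotational symmetry) it enumerates
#' plain combinations of the allowed slots in lexicographic order, scoring
#' them in vectorized batches. Exact ties are resolved in favour of the
#' first (lexicographically smallest) mask.
#'
#' @param n Number of measurements.
#' @param n_t Partition coarseness.
#' @param frequencies Frequencies of interest.
#' @param allowed Optional binary/logical vector of length `n_t`; `TRUE`/1
#'   marks slots where collection is permitted. See [rest_window_mask()].
#' @param cap Maximum number of candidate masks the search will accept
#'   (guards runtime); exceeeding it is an error.
#' @param batch Number of candidates scored per vectorized batch.
#' @return An `optimization_result` with the winning [design()], its mask,
#'   objective value, method metadata and an exhaustiveness certificate.
#' @export
optimize_brute <- function(n, n_t, frequencies, allowed = NULL,
                           cap = 2e7, batch = 5e5) {
  n <- as.integer(n); n_t <- as.integer(n_t)
  if (is.null(allowed)) {
    total <- count_necklaces(n, n_t)
    if (total > cap) {
      rlang::abort(sprintf("search space (%g necklaces) exceeds cap %g", total, cap),
        class = "rhythmdesign_error_cap")
    }
    masks <- enumerate_necklaces(n, n_t)
    idx <- apply(masks == 1L, 2, which)
    if (n == 1L) idx <- matrix(idx, nrow = 1)
    xi <- xi_min_batch_slots(idx, n_t, frequencies)
    best <- which.max(xi)
    best_mask <- masks[, best]
    n_eval <- ncol(masks)
  } else {
    allowed <- as.logical(allowed)
    if (length(allowed) != n_t) rlang::abort("allowed must have length n_t")
    slots <- which(allowed)
    if (length(slots) < n) {
      rlang::abort("infeasible constraint: fewer allowed slots than measurements",
        class = "rhythmdesign_error_infeasible")
    }
    total <- choose(length(slots), n)
    if (total > cap) {
      rlang::abort(sprintf("search space (%g masks) exceeds cap %g", total, cap),
        class = "rhythmdesign_error_cap")
    }
    best_xi <- -Inf
    best_slots <- NULL
    n_batches <- ceiling(total / batch)
    for (bb in seq_len(n_batches)) {
      r0 <- (bb - 1) * batch
      r1 <- min(total, bb * batch) - 1
      combos <- comb_unrank(r0:r1, length(slots), n) # n x B, lexicographic
      idx <- matrix(slots[combos], n)
      xi <- xi_min_batch_slots(idx, n_t, frequencies)
      w <- which.max(xi)
      if (xi[w] > best_xi) { # strict: earliest (lex-smallest) mask wins ties
        best_xi <- xi[w]
        best_slots <- idx[, w]
      }
    }
    best_mask <- integer(n_t)
    best_mask[best_slots] <- 1L
    n_eval <- total
  }
  d <- design_from_mask(best_mask, n_t)
  new_optimization_result(
    design = d,
    objective = multifreq_objective(d, frequencies)$j_value,
    method = "brute_force",
    mask = best_mask, n_t = n_t, frequencies = frequencies,
    exhaustive = TRUE, n_evaluated = n_eval
  )
}

#' Rest-window constraint mask on a uniform partition
#'
#' Marks the grid slots at which collection is permitted, excluding the
#' half-open rest window `[start, end)` (unit-interval times; a window
#' wrapping past 1 is allowed).
#'
#' @param n_t Partition coarseness.
#' @param start,end Window bounds as fractions of the study interval.
#' @return Logical vector of length `n_t` (`TRUE` = collection permitted).
#' @export
rest_window_mask <- function(n_t, start, end) {
  t <- (0:(n_t - 1)) / n_t
  if (start <= end) {
    !(t >= start & t < end)
  } else { # wraps midnight
    !(t >= start | t < end)
  }
}

#' Naive equal-interval design under a rest-window constraint
#'
#' The benchmark layout that spreads all `n` measurements at equal
#' time-intervals across the allowed arc: the first measurement sits at the
#' end of the rest window, the last at its start (one cycle later), with
#' spacing `(1 - window length) / (n - 1)`. With an empty window this is the
#' equispaced design. Optionally snapped to an `n_t`-slot grid (with a
#' warning when snapping moves any point).
#'
#' @param n Number of measurements.
#' @param start,end Rest-window bounds as fractions of the study interval
#'   (no sampling strictly inside; the boundaries themselves are used).
#' @param n_t Optional grid to snap to.
#' @return A [design()].
#' @export
naive_constrained_design <- function(n, start, end, n_t = NULL) {
  width <- (end - start) %% 1
  if (width == 0 && start != end) width <- 1
  arc <- 1 - width
  if (arc <= 0) {
    rlang::abort("rest window leaves no allowed arc",
      class = "rhythmdesign_error_infeasible")
  }
  if (width == 0) {
    # unconstrained limit: plain equispaced design rotated to the reference time
    times <- ((0:(n - 1)) / n + end) %% 1
  } else if (n == 1) {
    times <- end %% 1
  } else {
    times <- (end + arc * (0:(n - 1)) / (n - 1)) %% 1
  }
  if (!is.null(n_t)) {
    snapped <- round(times * n_t) %% n_t / n_t
    if (max(abs(snapped - times)) > 1e-12) {
      rlang::warn("equal spacing is not realizable on the grid; snapped to nearest slots")
    }
    if (anyDuplicated(snapped)) {
      rlang::abort("snapping produced coincident slots; use a finer grid",
        class = "rhythmdesign_error_infeasible")
    }
    times <- snapped
  }
  design(times)
}

#' Test the equiphase property of a design at a frequency
#'
#' A design is equiphase at integer frequency `f` when its measurement
#' phases modulo the period `1/f` can be partitioned into equispaced sets:
#' for some divisor `g >= 3` of `n`, the phase multiset consists of groups
#' of `g` equally spaced values (each full group possibly repeated), so the
#' first and second trigonometric moment sums vanish and the design attains
#' the equispaced optimum `xi_min = n/2` at `f`.
#'
#' @param d A [design()].
#' @param frequency Positive integer frequency.
#' @param tol Phase matching tolerance.
#' @return Logical.
#' @export
is_equiphase <- function(d, frequency, tol = 1e-8) {
  d <- as_design(d)
  n <- attr(d, "n")
  if (frequency < 1 || frequency != round(frequency)) {
    rlang::abort("frequency must be a positive integer")
  }
  p <- (frequency * as.numeric(d)) %% 1
  gs <- rev(divisors_of(n))
  gs <- gs[gs >= 3]
  for (g in gs) {
    if (equiphase_at_g(p, g, tol)) return(TRUE)
  }
  FALSE
}

# phases p partition into equispaced g-sets (offsets free, multiplicity equal)
equiphase_at_g <- function(p, g, tol) {
  q <- (g * p) %% 1 # within-step residue; constant within one equispaced set
  # cluster residues circularly with resolution tol * g
  eps <- max(g * tol, 1e-12)
  o <- order(q)
  qs <- q[o]
  breaks <- which(diff(qs) > eps)
  grp <- rep(seq_len(length(breaks) + 1L), diff(c(0L, breaks, length(qs))))
  # merge the wrap-around cluster
  if (length(breaks) > 0 && (qs[1] + 1 - qs[length(qs)]) <= eps) {
    grp[grp == max(grp)] <- 1L
  }
  groups <- split(o, grp)
  for (members in groups) {
    m <- length(members)
    if (m %% g != 0L) return(FALSE)
    q0 <- q[members[1]]
    k <- round(g * p[members] - q0) %% g
    if (max(abs(g * p[members] - q0 - round(g * p[members] - q0))) > eps) return(FALSE)
    counts <- tabulate(k + 1L, nbins = g)
    if (any(counts != m / g)) return(FALSE)
  }
  TRUE
}

#' Construct an equiphase design for several integer frequencies
#'
#' Builds a design whose phases are equispaced (in the partition sense of
#' [is_equiphase()]) at every requested frequency, so the worst-case
#' objective attains its theoretical maximum `J = n/2` at all of them. The
#' construction factorizes `n` into one factor `g_f >= 3` per frequency and
#' superimposes, per frequency, an equispaced offset ladder with spacing
#' `1 / (g_f * f)`; the candidate is verified numerically and the search
#' backtracks over factor assignments until one passes.
#'
#' @param n Number of measurements; must admit a factorization into
#'   `length(frequencies)` factors, each at least 3.
#' @param frequencies Distinct positive integer frequencies.
#' @return A [design()] with `multifreq_objective(...)$j_value == n/2`.
#' @export
equiphase_design <- function(n, frequencies) {
  frequencies <- as.numeric(frequencies)
  if (any(frequencies < 1 | frequencies != round(frequencies))) {
    rlang::abort("frequencies must be positive integers")
  }
  if (anyDuplicated(frequencies)) rlang::abort("frequencies must be distinct")
  m <- length(frequencies)
  facs <- factorizations_into(n, m, min_factor = 3L)
  if (length(facs) == 0) {
    rlang::abort(sprintf(
      "no equiphase construction: %d does not factor into %d parts each >= 3", n, m),
      class = "rhythmdesign_error_construction")
  }
  for (fac in facs) {
    for (perm in perms_of(seq_len(m))) {
      g <- fac[perm]
      offs <- purrr::map2(g, frequencies, ~ (0:(.x - 1)) / (.x * .y))
      times <- Reduce(function(a, b) as.vector(outer(a, b, `+`)), offs) %% 1
      if (anyDuplicated(round(times / 1e-12)) > 0) next
      cand <- design(sort(times))
      j <- multifreq_objective(cand, frequencies)$j_value
      ok <- all(purrr::map_lgl(frequencies, ~ is_equiphase(cand, .x)))
      if (ok && abs(j - n / 2) <= 1e-8) return(cand)
    }
  }
  rlang::abort("no equiphase construction found for these frequencies",
    class = "rhythmdesign_error_construction")
}

# all multisets of m factors (each >= min_factor) with product n, as lists
factorizations_into <- function(n, m, min_factor = 3L) {
  if (m == 1L) {
    if (n >= min_factor) return(list(n)) else return(list())
  }
  out <- list()
  for (g in divisors_of(n)) {
    if (g < min_factor) next
    if (n %/% g < min_factor^(m - 1L)) next
    rest <- factorizations_into(n %/% g, m - 1L, min_factor = g)
    for (r in rest) out[[length(out) + 1L]] <- c(g, r)
  }
  out
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# shared constructor for optimizer outputs
new_optimization_result <- function(design, objective, method, ...,
                                    trace = NULL, seed = NULL) {
  structure(
    list(design = design, objective = objective, method = method,
         trace = trace, seed = seed, meta = list(...)),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> method=%s  objective=%.6g  n=%d\n",
              x$method, x$objective, attr(x$design, "n")))
  if (!is.null(x$meta$exhaustive) && isTRUE(x$meta$exhaustive)) {
    cat(sprintf("  exhaustive search over %g candidates\n", x$meta$n_evaluated))
  }
  invisible(x)
}

#' @export
tidy.optimization_result <- function(x, ...) {
  if (is.null(x$trace)) {
    tibble::tibble(generation = integer(), best_objective = numeric())
  } else {
    tibble::tibble(generation = seq_along(x$trace), best_objective = x$trace)
  }
}

#' @export
glance.optimization_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    objective = x$objective,
    n = attr(x$design, "n"),
    exhaustive = isTRUE(x$meta$exhaustive),
    n_evaluated = x$meta$n_evaluated %||% NA_real_
  )
}
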