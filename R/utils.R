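# internal helpers shared across modules

# run expr under a temporary RNG seed without disturbing the caller's stream
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# condition-number threshold above which X'X is treated as singular
.SINGULAR_KAPPA <- 1e12

abort_singular <- function(frequency) {
  rlang::abort(
    sprintf(
      "design matrix is numerically singular at frequency %g (condition number > %g)",
      frequency, .SINGULAR_KAPPA
    ),
    class = "rhythmdesign_error_singular"
  )
}

is_singular_xtx <- function(xtx) {
  ev <- eigen(xtx, symmetric = TRUE, only.values = TRUE)$values
  ev[1] <= 0 || ev[3] <= 0 || ev[1] / max(ev[3], .Machine$double.xmin) > .SINGULAR_KAPPA
}

# smallest eigenvalue of a symmetric 2x2 matrix [[a, b], [b, d]], closed form
eig_min_2x2 <- function(a, b, d) {
  (a + d) / 2 - sqrt(((a - d) / 2)^2 + b^2)
}

# unrank lexicographic k-combinations of {1..n}: ranks are 0-based, returns a
# k x length(ranks) integer matrix of 1-based elements (combinatorial number
# system; one findInterval per row, so batches vectorize)
comb_unrank <- function(ranks, n, k) {
  B <- length(ranks)
  out <- matrix(0L, k, B)
  # decode rank C-1-r in the decreasing combinadic, then complement: the
  # result is the r-th combination in lexicographic order (verified against
  # utils::combn)
  rr <- choose(n, k) - 1 - ranks
  for (pos in seq_len(k)) {
    j <- k - pos + 1L
    tab <- choose(0:(n - 1), j)
    m <- findInterval(rr, tab) - 1L
    out[pos, ] <- m
    rr <- rr - tab[m + 1L]
  }
  # out rows are decreasing 0-based; convert to increasing 1-based complement
  out <- (n - 1L) - out
  storage.mode(out) <- "integer"
  out + 1L
}

divisors_of <- function(n) {
  d <- seq_len(n)
  d[n %% d == 0L]
}

euler_phi <- function(n) {
  if (n == 1L) return(1L)
  p <- unique(factorize_small(n))
  r <- n
  for (q in p) r <- r / q * (q - 1)
  as.integer(round(r))
}

factorize_small <- function(n) {
  f <- integer(0)
  d <- 2L
  while (d * d <= n) {
    while (n %% d == 0L) {
      f <- c(f, d)
      n <- n %/% d
    }
    d <- d + 1L
  }
  if (n > 1L) f <- c(f, as.integer(n))
  f
}
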