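# independent oracles used to pin expected values; deliberately naive
# implementations kept separate from the package's computational paths

# scalar-loop cosinor design matrix
oracle_design_matrix <- function(t, f) {
  out <- matrix(0, length(t), 3)
  for (i in seq_along(t)) {
    out[i, 1] <- 1
    out[i, 2] <- cos(2 * pi * f * t[i])
    out[i, 3] <- sin(2 * pi * f * t[i])
  }
  out
}

# normal-equation least squares via explicit 3x3 inversion
oracle_fit_beta <- function(y, t, f) {
  X <- oracle_design_matrix(t, f)
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# noncentrality by direct evaluation of the defining quadratic form
oracle_noncentrality <- function(t, f, A, phi, sigma) {
  X <- oracle_design_matrix(t, f)
  H <- rbind(c(0, 1, 0), c(0, 0, 1))
  beta <- c(0, A * cos(phi), A * sin(phi))
  M <- H %*% solve(t(X) %*% X) %*% t(H)
  drop(t(beta) %*% t(H) %*% solve(M) %*% H %*% beta) / sigma^2
}

# inverse of H (X'X)^-1 H' by explicit inversion (well-conditioned designs)
oracle_b_inverse <- function(t, f) {
  X <- oracle_design_matrix(t, f)
  H <- rbind(c(0, 1, 0), c(0, 0, 1))
  solve(H %*% solve(t(X) %*% X) %*% t(H))
}

# smallest eigenvalue of X' diag(mu) X at one frequency, full eigen
oracle_xi3 <- function(slots_idx, n_t, f) {
  t <- (slots_idx - 1) / n_t
  X <- oracle_design_matrix(t, f)
  min(eigen(t(X) %*% X, symmetric = TRUE, only.values = TRUE)$values)
}

# exhaustive max over all n-subsets of the n_t grid of min_f xi3
oracle_micp_optimum <- function(n, n_t, freqs) {
  combos <- utils::combn(n_t, n)
  best <- -Inf
  for (j in seq_len(ncol(combos))) {
    v <- min(vapply(freqs, function(f) oracle_xi3(combos[, j], n_t, f), numeric(1)))
    if (v > best) best <- v
  }
  best
}

# exhaustive max over all n-subsets of allowed slots of min_f xi_min(B^-1)
oracle_brute_optimum <- function(n, n_t, freqs, slots = seq_len(n_t)) {
  combos <- utils::combn(slots, n)
  best <- -Inf
  for (j in seq_len(ncol(combos))) {
    d <- design((combos[, j] - 1) / n_t)
    v <- min(vapply(freqs, function(f) worstcase_eigenvalue(d, f), numeric(1)))
    if (v > best) best <- v
  }
  best
}

# rotation-class count by canonical-form deduplication of all masks
oracle_necklace_count <- function(n, n_t) {
  combos <- utils::combn(n_t, n)
  canon <- character(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    mask <- integer(n_t)
    mask[combos[, j]] <- 1L
    rots <- vapply(seq_len(n_t) - 1L, function(s) {
      paste(mask[((seq_len(n_t) - 1L + s) %% n_t) + 1L], collapse = "")
    }, character(1))
    canon[j] <- min(rots)
  }
  length(unique(canon))
}

# all-pairs AUC
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# random non-singular design of size n at frequency f (resamples as needed)
random_design <- function(n, f = 1) {
  repeat {
    d <- design(sort(stats::runif(n)))
    ok <- tryCatch({
      design_matrix(d, f)
      xtx <- crossprod(design_matrix(d, f))
      kappa(xtx, exact = TRUE) < 1e10
    }, error = function(e) FALSE)
    if (ok) return(d)
  }
}
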