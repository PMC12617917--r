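test_that("design matrix matches trigonometric evaluation", {
  expect_equal(
    design_matrix(design(c(0, 0.25, 0.5, 0.75)), 1),
    cbind(1, c(1, 0, -1, 0), c(0, 1, 0, -1)),
    tolerance = 1e-12
  )
  expect_equal(design_matrix(design(0), 7), cbind(1, 1, 0))
  set.seed(42)
  d <- random_design(24)
  expect_equal(design_matrix(d, 3), oracle_design_matrix(as.numeric(d), 3),
               tolerance = 1e-12)
})

test_that("design constructor validates and sorts", {
  expect_equal(as.numeric(design(c(0.5, 0.1))), c(0.1, 0.5))
  expect_error(design(c(0.2, 1.0)), class = "rhythmdesign_error_design")
  expect_error(design(c(0.2, 0.2)), class = "rhythmdesign_error_design")
  expect_silent(design(c(0.2, 0.2), allow_duplicates = TRUE))
  expect_equal(nyquist_rate(design_equispaced(40)), 20)
  m <- design_to_mask(design_equispaced(4), 8)
  expect_equal(m, c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  expect_equal(as.numeric(design_from_mask(m, 8)), c(0, 0.25, 0.5, 0.75))
})

test_that("fixed-period fit recovers exact signals and matches normal equations", {
  d <- design(c(0, 0.25, 0.5, 0.75))
  y <- 2 + cos(2 * pi * as.numeric(d))
  fit <- fit_cosinor(y, d, 1)
  expect_equal(unname(fit$coefficients), c(2, 1, 0), tolerance = 1e-10)
  expect_equal(fit$amplitude, 1, tolerance = 1e-10)
  expect_equal(fit$acrophase, 0, tolerance = 1e-10)

  fitc <- fit_cosinor(rep(3.7, 4), d, 1)
  expect_equal(unname(fitc$coefficients), c(3.7, 0, 0), tolerance = 1e-10)
  expect_equal(fitc$amplitude, 0, tolerance = 1e-10)

  set.seed(7)
  d8 <- random_design(8)
  y8 <- rnorm(8)
  fit8 <- fit_cosinor(y8, d8, 1)
  expect_equal(unname(fit8$coefficients), oracle_fit_beta(y8, as.numeric(d8), 1),
               tolerance = 1e-10)
  # residual orthogonality
  X <- design_matrix(d8, 1)
  expect_lt(max(abs(crossprod(X, y8 - fit8$fitted))), 1e-8)
  expect_lte(fit8$rss, fit8$tss + 1e-10)
})

test_that("amplitude/acrophase round-trip through the linear coefficients", {
  set.seed(11)
  for (i in 1:100) {
    A <- runif(1, 0.1, 5)
    phi <- runif(1, 0, 2 * pi)
    b <- c(A * cos(phi), A * sin(phi))
    expect_equal(sqrt(sum(b^2)), A, tolerance = 1e-10)
    expect_equal(atan2(b[2], b[1]) %% (2 * pi), phi %% (2 * pi), tolerance = 1e-10)
  }
})

test_that("free-period fit selects the RSS-minimizing grid frequency", {
  d <- design_equispaced(16)
  y <- cos(2 * pi * 3 * as.numeric(d) - 1)
  fit <- fit_cosinor_free(y, d, 1, 5, n_freq = 81)
  expect_equal(fit$frequency, 3, tolerance = 0.051)

  set.seed(3)
  y2 <- cos(2 * pi * 2.5 * as.numeric(d)) + rnorm(16)
  grid <- c(1, 2, 3)
  rss <- vapply(grid, function(f) fit_cosinor(y2, d, f)$rss, numeric(1))
  fit2 <- fit_cosinor_free(y2, d, 1, 3, n_freq = 3)
  expect_equal(fit2$frequency, grid[which.min(rss)])

  set.seed(4)
  yw <- rnorm(16)
  fitw <- fit_cosinor_free(yw, d, 1, 6, n_freq = 21)
  prof <- attr(fitw, "profile")
  expect_true(all(fitw$rss <= prof$rss[!is.na(prof$rss)] + 1e-12))
})

test_that("equispaced trigonometric moments are orthogonal below Nyquist", {
  for (n in c(5, 8, 12, 24)) {
    d <- design_equispaced(n)
    for (f in seq_len(ceiling(n / 2) - 1)) {
      xtx <- crossprod(design_matrix(d, f))
      expect_equal(xtx, diag(c(n, n / 2, n / 2)), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("simulator reproduces the mean curve and honours seeds", {
  d <- design_equispaced(12)
  p <- cosinor_params(2, 3, acrophase = 1.2, mesor = 5, sigma = 1e-12)
  y <- simulate_rhythm(d, p, seed = 1)
  mu <- 5 + 2 * cos(2 * pi * 3 * as.numeric(d) - 1.2)
  expect_equal(y, mu, tolerance = 1e-9)

  dsq <- design_equispaced(200)
  psq <- cosinor_params(2, 1, acrophase = 0, sigma = 1e-15)
  ysq <- simulate_rhythm(dsq, psq, waveform("square"), seed = 2)
  expect_true(all(abs(ysq) < 1e-9 | abs(ysq - 2) < 1e-9))
  expect_equal(mean(ysq > 1), 0.5, tolerance = 0.02)

  yburst <- simulate_rhythm(dsq, psq, waveform("burst"), seed = 2)
  expect_equal(mean(yburst > 1), 0.25, tolerance = 0.02)

  pn <- cosinor_params(1, 2, sigma = 0.7)
  y1 <- simulate_rhythm(d, pn, seed = 99)
  y2 <- simulate_rhythm(d, pn, seed = 99)
  y3 <- simulate_rhythm(d, pn, seed = 100)
  expect_identical(y1, y2)
  expect_false(identical(y1, y3))
  for (kind in c("amplitude_modulated", "rhythmic_noise")) {
    expect_length(simulate_rhythm(d, pn, waveform(kind), seed = 5), 12)
  }
})

test_that("monte-carlo mean of the cosinor simulator matches the mean curve", {
  d <- design_equispaced(6)
  p <- cosinor_params(1.5, 2, acrophase = 0.8, mesor = 1, sigma = 1)
  nsim <- 4000
  set.seed(21)
  sims <- replicate(nsim, simulate_rhythm(d, p))
  mu <- 1 + 1.5 * cos(2 * pi * 2 * as.numeric(d) - 0.8)
  expect_true(all(abs(rowMeans(sims) - mu) <= 4 / sqrt(nsim)))
})
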