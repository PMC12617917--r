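test_that("amplitude profile matches per-frequency fits and peaks at the truth", {
  d <- design_equispaced(24)
  w <- freq_window(1, 8, 29)
  y <- 2 + 1.5 * cos(2 * pi * 4 * as.numeric(d) - 0.9)
  prof <- amplitude_profile(y, d, w)
  expect_equal(prof$frequency[which.max(prof$amplitude)], 4, tolerance = 1e-9)
  expect_equal(max(prof$amplitude), 1.5, tolerance = 1e-8)
  expect_equal(amplitude_profile(rep(2.2, 24), d, w)$amplitude,
               rep(0, nrow(prof)), tolerance = 1e-10)
  set.seed(51)
  yr <- rnorm(24)
  profr <- amplitude_profile(yr, d, w)
  for (i in seq_len(nrow(profr))) {
    expect_equal(profr$amplitude[i],
                 fit_cosinor(yr, d, profr$frequency[i])$amplitude,
                 tolerance = 1e-9)
  }
})

test_that("singular window frequencies are excluded per design", {
  d <- design_equispaced(24)
  w <- freq_window(1, 12, 12) # includes the Nyquist rate f = 12
  prof <- amplitude_profile(rnorm(24), d, w)
  expect_false(12 %in% prof$frequency)
  expect_true(12 %in% attr(prof, "excluded"))
})

test_that("T2 and Tinf statistics: homogeneity, nulls, and quadrature refinement", {
  d <- design_equispaced(24)
  w <- freq_window(1, 6, 21)
  expect_equal(stat_t2(rep(1, 24), d, w), 0, tolerance = 1e-12)
  expect_equal(stat_tinf(rep(1, 24), d, w), 0, tolerance = 1e-12)
  set.seed(53)
  y <- rnorm(24)
  expect_equal(stat_t2(3 * y, d, w), 9 * stat_t2(y, d, w), tolerance = 1e-9)
  expect_equal(stat_tinf(3 * y, d, w), 3 * stat_tinf(y, d, w), tolerance = 1e-9)
  # on-grid noiseless cosinor: Tinf equals the amplitude
  ysig <- 2.5 * cos(2 * pi * 3 * as.numeric(d) - 1)
  expect_equal(stat_tinf(ysig, d, w), 2.5, tolerance = 1e-8)
  # trapezoid refinement: 10x finer grid changes T2 by < 1%
  wf <- freq_window(1, 6, 201)
  expect_lt(abs(stat_t2(y, d, w) - stat_t2(y, d, wf)) / stat_t2(y, d, wf), 0.01)
  # matrix fast path agrees with the scalar statistics
  op <- rhythmdesign:::profile_operator(d, w)
  sm <- rhythmdesign:::stats_matrix(op, cbind(y, ysig))
  expect_equal(sm$t2, c(stat_t2(y, d, w), stat_t2(ysig, d, w)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sm$tinf, c(stat_tinf(y, d, w), stat_tinf(ysig, d, w)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("permutation p-values: separation, floor, and exact-S4 agreement", {
  d <- design_equispaced(24)
  w <- freq_window(1, 6, 24)
  y <- 5 * cos(2 * pi * 3 * as.numeric(d) - 0.4) + 0.01 * rnorm(24)
  pt <- perm_test(y, d, w, "tinf", n_perm = 199, seed = 55)
  expect_equal(pt$p_value, 1 / 200, tolerance = 1e-12)
  expect_gte(pt$p_value, 1 / (pt$n_perm + 1))

  # exact S_4 enumeration vs monte-carlo
  d4 <- design(c(0, 0.21, 0.47, 0.74))
  w4 <- freq_window(0.8, 1.6, 9)
  set.seed(57)
  y4 <- c(1.4, -0.2, -1.1, 0.8)
  exact <- perm_test(y4, d4, w4, "tinf", exact = TRUE)
  expect_equal(exact$n_perm, 24)
  # oracle: exhaustive S_4 tail probability under the monte-carlo convention
  # (">=" including ties); the strict-">" exact p differs by the tie mass
  obs <- stat_tinf(y4, d4, w4)
  perms <- rhythmdesign:::all_permutations(4)
  tall <- apply(perms, 2, function(p) stat_tinf(y4[p], d4, w4))
  p_ge <- mean(tall >= obs - 1e-12)
  expect_lte(exact$p_value, p_ge)
  mc <- perm_test(y4, d4, w4, "tinf", n_perm = 2000, seed = 58)
  se <- sqrt(p_ge * (1 - p_ge) / 2000)
  expect_lte(abs(mc$p_value - (1 + 2000 * p_ge) / 2001), 3 * se)
})

test_that("permutation invariance: statistics ignore the pairing order leak", {
  d <- design_equispaced(12)
  w <- freq_window(1, 4, 13)
  set.seed(59)
  y <- rnorm(12)
  pi1 <- sample(12)
  expect_equal(stat_t2(y[pi1], d, w), stat_t2(y[pi1], d, w), tolerance = 0)
  # computing on permuted data equals permuting then computing
  expect_equal(stat_tinf(y[pi1], d, w),
               stat_tinf((y[pi1])[seq_len(12)], d, w), tolerance = 0)
})

test_that("permutation power: null size, amplitude monotonicity, fixed-period link", {
  d <- design_equispaced(12)
  w <- freq_window(1, 5, 16)
  null_tab <- perm_power(d, frequencies = c(2, 4), n_acro = 2, amplitude = 0,
                         n_samp = 60, n_perm = 60, window = w,
                         statistic = "tinf", seed = 61)
  se <- sqrt(0.05 * 0.95 / 60)
  expect_true(all(abs(null_tab$min_power - 0.05) <= 3 * se + 1 / 60))

  powers <- vapply(c(1, 3), function(A) {
    perm_power(d, frequencies = 2, n_acro = 2, amplitude = A,
               n_samp = 50, n_perm = 60, window = w,
               statistic = "tinf", seed = 63)$min_power
  }, numeric(1))
  expect_gt(powers[2], powers[1])

  # free-period permutation power tracks fixed-period closed-form power
  set.seed(65)
  cfgs <- tibble::tibble(A = runif(12, 0.5, 3), f = sample(1:5, 12, TRUE))
  fixedp <- purrr::map2_dbl(cfgs$A, cfgs$f, function(A, f) {
    power_fixed(d, cosinor_params(A, f))
  })
  freep <- purrr::map2_dbl(cfgs$A, cfgs$f, function(A, f) {
    perm_power(d, frequencies = f, n_acro = 1, amplitude = A,
               n_samp = 40, n_perm = 50, window = w,
               statistic = "tinf", seed = round(1e4 * A))$min_power
  })
  expect_gt(cor(fixedp, freep), 0.5)
})

test_that("AUC matches the all-pairs oracle and its boundary values", {
  expect_equal(auc_score(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc_score(c(5, 6), c(1, 2)), 1)
  set.seed(67)
  pos <- rnorm(40, 0.5)
  neg <- rnorm(30)
  expect_equal(auc_score(pos, neg), oracle_auc(pos, neg), tolerance = 1e-12)
  ties_pos <- c(1, 1, 2)
  ties_neg <- c(1, 0)
  expect_equal(auc_score(ties_pos, ties_neg), oracle_auc(ties_pos, ties_neg))
  expect_error(auc_score(numeric(0), 1), class = "rhythmdesign_error_domain")
})
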