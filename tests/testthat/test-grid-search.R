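test_that("necklace counting matches direct enumeration", {
  expect_equal(count_necklaces(1, 5), 1)
  expect_equal(count_necklaces(1, 12), 1)
  expect_equal(count_necklaces(2, 4), 2)
  expect_equal(count_necklaces(4, 8), 10)
  for (nt in c(6, 9, 12)) {
    for (n in seq_len(nt)) {
      expect_equal(count_necklaces(n, nt), oracle_necklace_count(n, nt),
                   info = sprintf("n=%d nt=%d", n, nt))
    }
  }
  expect_error(count_necklaces(5, 4), class = "rhythmdesign_error_domain")
})

test_that("necklace enumeration yields one canonical representative per class", {
  for (nt in 2:16) {
    for (n in seq_len(nt)) {
      masks <- enumerate_necklaces(n, nt)
      expect_equal(ncol(masks), count_necklaces(n, nt),
                   info = sprintf("n=%d nt=%d", n, nt))
      keys <- apply(masks, 2, paste, collapse = "")
      expect_false(anyDuplicated(keys) > 0)
      # every column is its own lexicographically smallest rotation
      for (j in seq_len(ncol(masks))) {
        expect_equal(rhythmdesign:::canonical_rotation(masks[, j]), masks[, j])
      }
      expect_true(all(colSums(masks) == n))
    }
  }
})

test_that("brute-force search matches a plain-loop oracle and finds equispaced optima", {
  res <- optimize_brute(4, 8, 1)
  expect_equal(res$objective, 2, tolerance = 1e-10)
  expect_true(isTRUE(res$meta$exhaustive))

  res2 <- optimize_brute(5, 10, c(1, 2))
  expect_equal(res2$objective, oracle_brute_optimum(5, 10, c(1, 2)),
               tolerance = 1e-10)

  allowed <- rest_window_mask(12, 0, 1 / 3)
  res3 <- optimize_brute(4, 12, 1, allowed = allowed)
  expect_equal(res3$objective,
               oracle_brute_optimum(4, 12, 1, slots = which(allowed)),
               tolerance = 1e-10)
  expect_true(all(as.logical(res3$mask) <= allowed))

  expect_error(optimize_brute(8, 48, 1, allowed = rep(TRUE, 48), cap = 100),
               class = "rhythmdesign_error_cap")
  expect_error(optimize_brute(5, 12, 1, allowed = rep(c(TRUE, FALSE, FALSE), 4)),
               class = "rhythmdesign_error_infeasible")
})

test_that("brute-force search is invariant to rotating partition and constraint", {
  allowed <- rest_window_mask(16, 0, 0.25)
  base <- optimize_brute(4, 16, 1, allowed = allowed)
  rot <- c(allowed[-(1:4)], allowed[1:4]) # constraint rotated by 4 slots
  shifted <- optimize_brute(4, 16, 1, allowed = rot)
  expect_equal(base$objective, shifted$objective, tolerance = 1e-10)
})

test_that("naive rest-window design spans the allowed arc and degrades gracefully", {
  dn <- naive_constrained_design(8, 0, 1 / 3)
  t <- as.numeric(dn)
  expect_equal(min(t), 0) # last point wraps onto the window start boundary
  expect_equal(sort((t - 1 / 3) %% 1)[1:2], c(0, 2 / 21), tolerance = 1e-12)
  expect_equal(diff(sort((t - 1 / 3) %% 1)), rep(2 / 21, 7), tolerance = 1e-12)

  deq <- naive_constrained_design(4, 0.2, 0.2)
  expect_equal(as.numeric(deq), sort((0.2 + (0:3) / 4) %% 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_warning(naive_constrained_design(5, 0, 0.5, n_t = 12))
  expect_error(naive_constrained_design(3, 0, 1),
               class = "rhythmdesign_error_infeasible")
})

test_that("optimal constrained designs dominate naive ones", {
  for (width in c(0.25, 1 / 3, 0.4, 0.5)) {
    allowed <- rest_window_mask(48, 0, width)
    opt <- optimize_brute(6, 48, 1, allowed = allowed)
    naive <- naive_constrained_design(6, 0, width)
    expect_gte(opt$objective + 1e-9,
               multifreq_objective(naive, 1)$j_value)
  }
})

test_that("equiphase construction reaches the N/2 optimum at every frequency", {
  d <- equiphase_design(12, c(1, 12))
  obj <- multifreq_objective(d, c(1, 12))
  expect_equal(obj$j_value, 6, tolerance = 1e-8)
  expect_equal(obj$per_frequency$xi_min, c(6, 6), tolerance = 1e-8)
  expect_true(is_equiphase(d, 1))
  expect_true(is_equiphase(d, 12))

  d1 <- equiphase_design(4, 1)
  expect_equal(as.numeric(d1), c(0, 0.25, 0.5, 0.75), tolerance = 1e-12,
               ignore_attr = TRUE)

  d3 <- equiphase_design(36, c(1, 4, 10))
  expect_equal(multifreq_objective(d3, c(1, 4, 10))$j_value, 18, tolerance = 1e-8)
  for (f in c(1, 4, 10)) expect_true(is_equiphase(d3, f))

  expect_error(equiphase_design(8, c(1, 5)),
               class = "rhythmdesign_error_construction")
})

test_that("is_equiphase distinguishes genuine and collapsed phase layouts", {
  expect_true(is_equiphase(design_equispaced(8), 1))
  expect_false(is_equiphase(design_equispaced(8), 4)) # phases collapse to 2 values
  # rotated equispaced still equiphase
  expect_true(is_equiphase(design_equispaced(8, offset = 0.123), 1))
  # random designs are essentially never equiphase
  set.seed(41)
  expect_false(is_equiphase(design(sort(runif(8))), 1))
})
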