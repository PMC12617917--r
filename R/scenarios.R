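#' Run a packaged analysis scenario end to end
#'
#' Reproduces the package's benchmark analyses from a single configuration
#' list and writes designs (CSV), result tables (CSV) and a JSON summary of
#' the headline numbers into `out_dir`. Scenarios:
#'
#' * `rest_window`: naive vs brute-force-optimal designs under rest windows
#'   of several durations, with peak-to-trough power variability and the
#'   noncentrality parameter relative to an unconstrained equispaced design.
#' * `bifrequency` / `trifrequency`: equiphase construction for two or
#'   three integer frequencies, verified against the `n/2` optimum.
#' * `nyquist_window`: seeded differential evolution over a frequency window
#'   containing the Nyquist rate, compared with the equispaced design.
#' * `jitter`: jitter-robustness curve for a design.
#' * `permpower`: permutation-test power grid for a design.
#'
#' @param config Named list: `scenario` plus scenario parameters (see the
#'   defaults in the implementation); stochastic scenarios require `seed`.
#' @param out_dir Output directory (created if missing).
#' @return The summary list, invisibly; also written as `summary.json`.
#' @export
run_scenario <- function(config, out_dir = ".") {
  if (is.null(config$scenario)) {
    rlang::abort("config$scenario is required", class = "rhythmdesign_error_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- switch(config$scenario,
    rest_window = scenario_rest_window(config, out_dir),
    bifrequency = scenario_equiphase(config, out_dir, 2L),
    trifrequency = scenario_equiphase(config, out_dir, 3L),
    nyquist_window = scenario_nyquist(config, out_dir),
    jitter = scenario_jitter(config, out_dir),
    permpower = scenario_permpower(config, out_dir),
    rlang::abort(sprintf("unknown scenario '%s'", config$scenario),
      class = "rhythmdesign_error_config")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

cfg <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

scenario_rest_window <- function(config, out_dir) {
  n <- cfg(config, "n", 8L)
  n_t <- cfg(config, "n_t", 48L)
  windows <- cfg(config, "window_hours", c(6, 8, 10, 12))
  study_hours <- cfg(config, "study_hours", 24)
  amplitude <- cfg(config, "amplitude", 2.5)
  alpha <- cfg(config, "alpha", 0.05)
  n_phase <- cfg(config, "n_phase", 512L)
  f <- cfg(config, "frequency", 1)
  # reference: worst-case noncentrality of the unconstrained equispaced design
  lam_ref <- amplitude^2 * worstcase_eigenvalue(design_equispaced(n), f)
  rows <- purrr::map(windows, function(w) {
    frac <- w / study_hours
    allowed <- rest_window_mask(n_t, 0, frac)
    if (sum(allowed) < n) {
      rlang::abort(sprintf("window of %g h leaves fewer than %d slots", w, n),
        class = "rhythmdesign_error_infeasible")
    }
    dn <- naive_constrained_design(n, 0, frac)
    dopt <- optimize_brute(n, n_t, f, allowed = allowed)$design
    scan_n <- worstcase_power_acrophase(dn, f, amplitude, alpha = alpha,
                                        n_phase = n_phase)
    scan_o <- worstcase_power_acrophase(dopt, f, amplitude, alpha = alpha,
                                        n_phase = n_phase)
    write_design(dn, file.path(out_dir, sprintf("naive_%gh.csv", w)))
    write_design(dopt, file.path(out_dir, sprintf("optimal_%gh.csv", w)))
    tibble::tibble(
      window_hours = w,
      delta_naive = scan_n$delta,
      delta_optimal = scan_o$delta,
      rel_lambda_naive = amplitude^2 * worstcase_eigenvalue(dn, f) / lam_ref,
      rel_lambda_optimal = amplitude^2 * worstcase_eigenvalue(dopt, f) / lam_ref
    )
  })
  tab <- dplyr::bind_rows(rows)
  readr::write_csv(tab, file.path(out_dir, "rest_window.csv"))
  list(scenario = "rest_window", table = tab)
}

scenario_equiphase <- function(config, out_dir, n_freq) {
  frequencies <- cfg(config, "frequencies",
                     if (n_freq == 2L) c(1, 12) else c(1, 12, 336))
  if (length(frequencies) != n_freq) {
    rlang::abort(sprintf("scenario expects %d frequencies", n_freq),
      class = "rhythmdesign_error_config")
  }
  n <- cfg(config, "n", if (n_freq == 2L) 12L else 48L)
  d <- equiphase_design(n, frequencies)
  obj <- multifreq_objective(d, frequencies)
  write_design(d, file.path(out_dir, "equiphase_design.csv"))
  readr::write_csv(tidy(obj), file.path(out_dir, "objective.csv"))
  list(
    scenario = if (n_freq == 2L) "bifrequency" else "trifrequency",
    n = n, frequencies = frequencies,
    j_value = obj$j_value,
    equiphase = all(purrr::map_lgl(frequencies, ~ is_equiphase(d, .x)))
  )
}

scenario_nyquist <- function(config, out_dir) {
  n <- cfg(config, "n", 12L)
  frequencies <- cfg(config, "frequencies", seq_len(n / 2))
  seed <- config$seed
  if (is.null(seed)) rlang::abort("stochastic scenario requires a seed",
    class = "rhythmdesign_error_config")
  res <- optimize_de(
    n, frequencies,
    pop_size = cfg(config, "pop_size", 200L),
    weight = cfg(config, "weight", 0.05),
    crossover = cfg(config, "crossover", 0.05),
    n_iter = cfg(config, "n_iter", 200L),
    seed = seed
  )
  eq <- design_equispaced(n)
  write_design(res$design, file.path(out_dir, "de_design.csv"))
  list(
    scenario = "nyquist_window", n = n, seed = seed,
    j_irregular = res$objective,
    j_equispaced = multifreq_objective(eq, frequencies)$j_value
  )
}

scenario_jitter <- function(config, out_dir) {
  d <- if (!is.null(config$design_file)) read_design(config$design_file)
       else design_equispaced(cfg(config, "n", 24L))
  seed <- config$seed
  if (is.null(seed)) rlang::abort("stochastic scenario requires a seed",
    class = "rhythmdesign_error_config")
  curve <- jitter_robustness(
    d,
    frequencies = cfg(config, "frequencies", 1:4),
    amplitude = cfg(config, "amplitude", 1),
    noise_grid = cfg(config, "noise_grid", c(0, 0.002, 0.005, 0.01, 0.02)),
    n_rep = cfg(config, "n_rep", 50L),
    seed = seed
  )
  readr::write_csv(curve, file.path(out_dir, "jitter_curve.csv"))
  list(scenario = "jitter", seed = seed, table = curve)
}

scenario_permpower <- function(config, out_dir) {
  d <- if (!is.null(config$design_file)) read_design(config$design_file)
       else design_equispaced(cfg(config, "n", 12L))
  seed <- config$seed
  if (is.null(seed)) rlang::abort("stochastic scenario requires a seed",
    class = "rhythmdesign_error_config")
  window <- freq_window(cfg(config, "f_min", 1),
                        cfg(config, "f_max", 6),
                        cfg(config, "n_grid", 24L))
  tab <- perm_power(
    d,
    frequencies = cfg(config, "frequencies", 1:6),
    n_acro = cfg(config, "n_acro", 4L),
    amplitude = cfg(config, "amplitude", 2),
    alpha = cfg(config, "alpha", 0.05),
    n_samp = cfg(config, "n_samp", 50L),
    n_perm = cfg(config, "n_perm", 100L),
    window = window,
    statistic = cfg(config, "statistic", "tinf"),
    seed = seed
  )
  readr::write_csv(tab, file.path(out_dir, "perm_power.csv"))
  list(scenario = "permpower", seed = seed, table = tab)
}
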