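#' Cosinor signal parameters
#'
#' Bundles the parameters of the single-component cosinor model
#' `Y(t) = mesor + amplitude * cos(2*pi*frequency*t - acrophase) + noise`,
#' with homoscedastic Gaussian noise of standard deviation `sigma`.
#'
#' @param amplitude Peak deviation from the MESOR (signal units), `>= 0`.
#' @param frequency Cycles per study interval, `> 0`.
#' @param acrophase Phase of the peak in radians; stored in `[0, 2*pi)`.
#' @param mesor Rhythm-adjusted mean (signal units).
#' @param sigma Noise standard deviation (signal units), `> 0`.
#' @return An object of class `cosinor_params`.
#' @export
cosinor_params <- function(amplitude, frequency, acrophase = 0, mesor = 0, sigma = 1) {
  stopifnot(is.numeric(amplitude), is.numeric(frequency))
  if (amplitude < 0) rlang::abort("amplitude must be >= 0")
  if (frequency <= 0) rlang::abort("frequency must be > 0")
  if (sigma < 0) rlang::abort("sigma must be >= 0 (power analysis requires > 0)")
  structure(
    list(
      mesor = mesor, amplitude = amplitude,
      acrophase = acrophase %% (2 * pi),
      frequency = frequency, sigma = sigma
    ),
    class = "cosinor_params"
  )
}

#' @export
print.cosinor_params <- function(x, ...) {
  cat(sprintf(
    "<cosinor_params> mesor=%g amplitude=%g acrophase=%g rad frequency=%g sigma=%g\n",
    x$mesor, x$amplitude, x$acrophase, x$frequency, x$sigma
  ))
  invisible(x)
}

# linear coefficients (beta0, beta1, beta2) of the linearized model
params_to_beta <- function(params) {
  c(
    params$mesor,
    params$amplitude * cos(params$acrophase),
    params$amplitude * sin(params$acrophase)
  )
}

#' Cosinor design matrix
#'
#' The `N x 3` regressor matrix `[1, cos(2*pi*f*t), sin(2*pi*f*t)]` of the
#' linearized cosinor model at the design's measurement times.
#'
#' @param d A [design()] (or numeric times).
#' @param frequency Frequency in cycles per study interval, `> 0`.
#' @return A numeric matrix with `N` rows and 3 columns.
#' @export
design_matrix <- function(d, frequency) {
  d <- as_design(d)
  if (frequency <= 0) rlang::abort("frequency must be > 0")
  t <- as.numeric(d)
  cbind(1, cos(2 * pi * frequency * t), sin(2 * pi * frequency * t))
}

#' Fit the fixed-period cosinor model by least squares
#'
#' Linear least squares of `y` on the cosinor design matrix at a known
#' frequency. Amplitude and acrophase estimates are recovered from the
#' linear coefficients as `A = sqrt(b1^2 + b2^2)` and
#' `phi = atan2(b2, b1)` (reported in `(-pi, pi]`).
#'
#' @param y Response vector, one value per design time.
#' @param d A [design()].
#' @param frequency Frequency in cycles per study interval.
#' @return A `cosinor_fit` with components `coefficients` (beta0, beta1,
#'   beta2), `amplitude`, `acrophase`, `frequency`, `rss`, `tss`, `fitted`,
#'   `n`. Use [glance()] / [tidy()] for tibble summaries.
#' @export
fit_cosinor <- function(y, d, frequency) {
  d <- as_design(d)
  n <- attr(d, "n")
  if (length(y) != n) {
    rlang::abort("length(y) must equal the design's sample size",
      class = "rhythmdesign_error_fit")
  }
  X <- design_matrix(d, frequency)
  xtx <- crossprod(X)
  if (is_singular_xtx(xtx)) abort_singular(frequency)
  beta <- drop(solve(xtx, crossprod(X, y)))
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      coefficients = stats::setNames(beta, c("beta0", "beta1", "beta2")),
      amplitude = sqrt(beta[2]^2 + beta[3]^2),
      acrophase = atan2(beta[3], beta[2]),
      frequency = frequency,
      rss = rss, tss = tss, fitted = fitted, n = n,
      design = d
    ),
    class = "cosinor_fit"
  )
}

#' Fit the free-period cosinor model by frequency grid search
#'
#' Profiles the residual sum of squares of the fixed-period fit over a
#' uniform frequency grid on `[f_min, f_max]` and returns the fit at the
#' RSS-minimizing grid frequency. Grid frequencies at which the design is
#' numerically singular are skipped.
#'
#' @inheritParams fit_cosinor
#' @param f_min,f_max Frequency window bounds, `0 < f_min < f_max`.
#' @param n_freq Number of grid frequencies (`>= 2`).
#' @return A `cosinor_fit` whose `frequency` is the selected grid frequency;
#'   the RSS profile is attached as attribute `profile` (a tibble).
#' @export
fit_cosinor_free <- function(y, d, f_min, f_max, n_freq = 100) {
  if (!(f_min > 0 && f_max > f_min)) rlang::abort("need 0 < f_min < f_max")
  if (n_freq < 2) rlang::abort("n_freq must be >= 2")
  freqs <- seq(f_min, f_max, length.out = n_freq)
  fits <- vector("list", n_freq)
  rssv <- rep(NA_real_, n_freq)
  for (i in seq_len(n_freq)) {
    fit <- tryCatch(fit_cosinor(y, d, freqs[i]),
      rhythmdesign_error_singular = function(e) NULL)
    if (!is.null(fit)) {
      fits[[i]] <- fit
      rssv[i] <- fit$rss
    }
  }
  if (all(is.na(rssv))) {
    rlang::abort("design is singular at every grid frequency",
      class = "rhythmdesign_error_singular")
  }
  best <- which.min(rssv)
  out <- fits[[best]]
  attr(out, "profile") <- tibble::tibble(frequency = freqs, rss = rssv)
  out
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> f=%g  A=%.4g  phi=%.4g rad  MESOR=%.4g  rss=%.4g (n=%d)\n",
    x$frequency, x$amplitude, x$acrophase, x$coefficients[1], x$rss, x$n
  ))
  invisible(x)
}

#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "beta_cos", "beta_sin"),
    estimate = unname(x$coefficients)
  )
}

#' @export
glance.cosinor_fit <- function(x, ...) {
  df2 <- x$n - 3
  fstat <- if (df2 > 0 && x$rss > 0) ((x$tss - x$rss) / 2) / (x$rss / df2) else NA_real_
  tibble::tibble(
    frequency = x$frequency,
    amplitude = x$amplitude,
    acrophase = x$acrophase,
    mesor = unname(x$coefficients[1]),
    rss = x$rss,
    tss = x$tss,
    statistic = fstat,
    df1 = 2,
    df2 = df2,
    nobs = x$n
  )
}

#' Waveform specification for synthetic signals
#'
#' Besides the standard cosinor, the simulator produces signal classes that
#' violate cosinor assumptions: amplitude-modulated cosinor, noise with
#' rhythmic intensity, square waves, and burst-like (short-duty) square
#' waves.
#'
#' @param kind One of `"cosinor"`, `"amplitude_modulated"`,
#'   `"rhythmic_noise"`, `"square"`, `"burst"`.
#' @param duty_cycle Fraction of the cycle spent high, for square-like
#'   waveforms. Defaults: 0.5 for `"square"`, 0.25 for `"burst"`.
#' @param env_rate,env_depth Envelope rate (cycles per interval) and relative
#'   depth of the amplitude modulation, used only by
#'   `"amplitude_modulated"`.
#' @return A `waveform` specification list.
#' @export
waveform <- function(kind = c("cosinor", "amplitude_modulated", "rhythmic_noise",
                              "square", "burst"),
                     duty_cycle = NULL, env_rate = 1, env_depth = 0.5) {
  kind <- rlang::arg_match(kind)
  if (is.null(duty_cycle)) {
    duty_cycle <- switch(kind, square = 0.5, burst = 0.25, NA_real_)
  }
  if (kind %in% c("square", "burst") && !(duty_cycle > 0 && duty_cycle < 1)) {
    rlang::abort("duty_cycle must be in (0, 1)")
  }
  structure(list(kind = kind, duty_cycle = duty_cycle,
                 env_rate = env_rate, env_depth = env_depth),
            class = "rhythm_waveform")
}

#' Simulate a rhythmic signal at the design's measurement times
#'
#' @param d A [design()].
#' @param params A [cosinor_params()].
#' @param wave A [waveform()]; defaults to the standard cosinor.
#' @param seed Optional integer seed for reproducibility; when given, the
#'   caller's RNG stream is left untouched.
#' @return Numeric vector of simulated observations, one per design time.
#' @export
simulate_rhythm <- function(d, params, wave = waveform("cosinor"), seed = NULL) {
  d <- as_design(d)
  if (!inherits(wave, "rhythm_waveform")) {
    rlang::abort("wave must be created with waveform()")
  }
  t <- as.numeric(d)
  n <- length(t)
  ph <- 2 * pi * params$frequency * t - params$acrophase
  with_seed_opt(seed, {
    z <- stats::rnorm(n)
    switch(wave$kind,
      cosinor = params$mesor + params$amplitude * cos(ph) + params$sigma * z,
      amplitude_modulated = {
        env <- 1 + wave$env_depth * cos(2 * pi * wave$env_rate * t)
        params$mesor + params$amplitude * env * cos(ph) + params$sigma * z
      },
      rhythmic_noise =
        params$mesor + params$sigma * z * (1 + params$amplitude * cos(ph)),
      square = ,
      burst = {
        high <- ((ph / (2 * pi)) %% 1) < wave$duty_cycle
        params$mesor + params$amplitude * as.numeric(high) + params$sigma * z
      }
    )
  })
}
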