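#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot power as a function of acrophase
#'
#' @param object An `acrophase_scan` from [worstcase_power_acrophase()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acrophase_scan <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$acrophase, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(
      breaks = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
      labels = c("0", "π/2", "π", "3π/2", "2π")
    ) +
    ggplot2::labs(
      x = "acrophase (rad)", y = "power",
      title = sprintf("Power vs acrophase at f = %g (Δ = %.2f pp)",
                      object$frequency, object$delta)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-frequency worst-case eigenvalue criterion
#'
#' @param object An `objective_report` from [multifreq_objective()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.objective_report <- function(object, ...) {
  ggplot2::ggplot(object$per_frequency,
                  ggplot2::aes(x = .data$frequency, y = .data$xi_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$n / 2, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$j_value, colour = "red") +
    ggplot2::labs(
      x = "frequency (cycles per interval)",
      y = expression(xi[min]),
      title = sprintf("Worst-case criterion (J = %.3f, bound N/2 = %g)",
                      object$j_value, object$n / 2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a jitter-robustness curve
#'
#' @param object A `jitter_curve` from [jitter_robustness()].
#' @param ... Unused.
#' @return A ggplot with the median worst-case power and interquartile band.
#' @export
autoplot.jitter_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$noise_sd, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "timing jitter SD (fraction of study interval)",
      y = "worst-case power",
      title = "Design robustness to measurement-time jitter"
    ) +
    ggplot2::theme_minimal()
}
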