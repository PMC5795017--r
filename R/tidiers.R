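# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @rdname classify_regime
#' @param x A `regime_report`.
#' @param ... Unused.
#' @method glance regime_report
#' @export
glance.regime_report <- function(x, ...) {
  r <- unclass(x)
  tibble(
    regime = r$regime, graded = r$graded, x = r$x,
    tau_sus = r$tau_sus, tau_pulsed = r$tau_pulsed,
    tau_pulsed_valid = r$tau_pulsed_valid, delay_factor = r$delay_factor,
    fast_boundary_K_A = r$fast_boundary_K_A,
    delay_boundary_K_A = r$delay_boundary_K_A,
    graded_boundary_K_A = r$graded_boundary_K_A
  )
}

#' @rdname classify_regime
#' @method tidy regime_report
#' @export
tidy.regime_report <- function(x, ...) {
  tibble(
    quantity = c("x", "tau_sus", "tau_pulsed", "delay_factor",
                 "fast_boundary_K_A", "delay_boundary_K_A",
                 "graded_boundary_K_A"),
    value = c(x$x, x$tau_sus, x$tau_pulsed, x$delay_factor,
              x$fast_boundary_K_A, x$delay_boundary_K_A,
              x$graded_boundary_K_A),
    unit = c("", "h", "h", "", "nM", "nM", "nM")
  )
}

#' @rdname titration_curve
#' @param x A `ph_titration` object.
#' @param ... Unused.
#' @method glance ph_titration
#' @export
glance.ph_titration <- function(x, ...) {
  tibble(
    n = attr(x, "n"), duty_cycle = attr(x, "duty_cycle"),
    k2T = attr(x, "k2T"), K_A = attr(x, "K_A"),
    half_saturation = attr(x, "half_saturation"),
    shift = attr(x, "shift")
  )
}

#' @rdname simulate_binding
#' @param x A `ph_trajectory`.
#' @param ... Unused.
#' @method glance ph_trajectory
#' @export
glance.ph_trajectory <- function(x, ...) {
  p <- attr(x, "params"); s <- attr(x, "forcing")
  tibble(
    n = p$n, k1 = p$k1, k2 = p$k2, K_A = p$K_A,
    amplitude = s$amplitude, period = s$period,
    duty_cycle = s$duty_cycle, method = attr(x, "method"),
    P_final = x$P[nrow(x)],
    P_mean_last_period = mean(x$P[x$time >= max(x$time) - s$period])
  )
}

#' Plot a binding trajectory
#'
#' Bound fraction over time with the square-wave signal (rescaled to the
#' unit interval) underlaid in grey.
#'
#' @param object A `ph_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ph_trajectory
#' @export
autoplot.ph_trajectory <- function(object, ...) {
  s <- attr(object, "forcing")
  amp <- max(s$amplitude, 1e-12)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$signal / amp),
                       color = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$P), color = "#2166ac",
                       linewidth = 0.7) +
    ggplot2::labs(
      x = "time (h)", y = "bound fraction P(t)",
      title = sprintf("n = %g, K_A = %g nM, A = %g nM, duty cycle %g",
                      attr(object, "params")$n, attr(object, "params")$K_A,
                      s$amplitude, s$duty_cycle),
      subtitle = "grey: signal (rescaled)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a titration curve
#'
#' Average binding versus average signal concentration on a log axis, with
#' the true and apparent (half-saturation) dissociation constants marked.
#'
#' @param object A `ph_titration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ph_titration
#' @export
autoplot.ph_titration <- function(object, ...) {
  gl <- glance(object)
  pl <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_signal,
                                             y = .data$mean_binding)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = gl$K_A, linetype = "dotted") +
    ggplot2::labs(
      x = "average signal concentration (nM)",
      y = "average binding at infinite time",
      title = sprintf("n = %g, duty cycle %g, k2T = %g",
                      gl$n, gl$duty_cycle, gl$k2T)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(gl$half_saturation)) {
    pl <- pl + ggplot2::geom_vline(xintercept = gl$half_saturation,
                                   linetype = "dashed", color = "#b2182b")
  }
  pl
}

#' Plot a scenario grid as a heatmap
#'
#' Binding probability over time (x) and dissociation constant (y, log
#' scale), with the fast-pulsing, delay and graded-clocking boundary
#' concentrations overlaid as dashed lines when they exist.
#'
#' @param object A `ph_grid` from [scenario_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ph_grid
#' @export
autoplot.ph_grid <- function(object, ...) {
  b <- attr(object, "boundaries")
  ban <- attr(object, "banner")
  pl <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$K_A,
                                             fill = .data$P)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      x = "time (h)", y = expression(K[A] ~ "(nM)"),
      title = sprintf("n = %g, A = %g nM, k1 = %g, duty cycle %g",
                      ban$n, ban$A, ban$k1, ban$duty_cycle)
    ) +
    ggplot2::theme_minimal()
  cols <- c(fast = "#8c510a", delay = "grey60", graded = "magenta")
  for (nm in names(cols)) {
    if (!is.na(b[[nm]])) {
      pl <- pl + ggplot2::geom_hline(yintercept = b[[nm]],
                                     linetype = "dashed",
                                     color = cols[[nm]])
    }
  }
  pl
}
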