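#' Square-wave pulsed signal
#'
#' Construct the square-wave forcing used throughout the package.  The
#' signal-molecule concentration is held at `amplitude` for the first
#' `duty_cycle * period` hours of every period (the pulse-on interval) and at
#' zero for the remainder.  On-intervals are half-open: the instant a pulse
#' starts belongs to the on-state, the instant it ends to the off-state.
#' `duty_cycle = 1` means sustained signaling — the signal never switches off.
#'
#' Units follow the conventions of the p53 application: concentrations in nM,
#' times in hours.
#'
#' @param amplitude Pulse amplitude \eqn{A} (nM), `>= 0`.
#' @param period Pulsing period \eqn{T} (h), `> 0`.
#' @param duty_cycle Duty cycle \eqn{\gamma} in `(0, 1]`, the fraction of each
#'   period during which the signal is on.  `duty_cycle = 0` is rejected (the
#'   signal would never appear).
#'
#' @return An object of class `square_wave` with fields `amplitude`, `period`,
#'   `duty_cycle` and the derived pulse-on duration `pulse_on`
#'   (\eqn{\Delta = \gamma T}).
#'
#' @examples
#' sw <- square_wave(amplitude = 10, period = 6, duty_cycle = 0.3)
#' signal_at(sw, c(0, 1, 1.8, 6))
#' mean_signal(sw)
#' @export
square_wave <- function(amplitude, period, duty_cycle) {
  check_number(amplitude, "amplitude", lower = 0)
  check_number(period, "period", lower = 0, allow_lower = FALSE)
  check_number(duty_cycle, "duty_cycle", lower = 0, upper = 1,
               allow_lower = FALSE)
  structure(
    list(
      amplitude = amplitude,
      period = period,
      duty_cycle = duty_cycle,
      pulse_on = duty_cycle * period
    ),
    class = "square_wave"
  )
}

#' @export
print.square_wave <- function(x, ...) {
  cat(sprintf(
    "<square_wave> A = %g nM, T = %g h, duty cycle = %g (pulse on %g h)%s\n",
    x$amplitude, x$period, x$duty_cycle, x$pulse_on,
    if (x$duty_cycle == 1) " [sustained]" else ""
  ))
  invisible(x)
}

#' Evaluate the signal concentration
#'
#' Returns the signal-molecule concentration \eqn{[S](t)}: `amplitude` while
#' the phase within the current period is in `[0, pulse_on)`, zero otherwise.
#'
#' @param signal A [square_wave()] object.
#' @param t Vector of times (h), all `>= 0`.
#' @return Numeric vector of concentrations (nM), same length as `t`.
#' @examples
#' signal_at(square_wave(10, 6, 0.3), c(0, 1.7, 1.8, 5.9, 6))
#' @export
signal_at <- function(signal, t) {
  stopifnot(inherits(signal, "square_wave"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    ph_abort("`t` must be finite numeric.")
  }
  if (any(t < 0)) ph_abort("`t` must be non-negative.")
  if (signal$duty_cycle == 1) {
    return(rep(signal$amplitude, length(t)))
  }
  pd <- phase_decomp(signal, t)
  ifelse(pd$on, signal$amplitude, 0)
}

# internal: robust (pulse, phase, on-state) decomposition.  Phases within a
# small tolerance of a switching instant are snapped onto it so that grid
# points constructed as k*T + Delta classify consistently despite rounding;
# the half-open convention places the switching instant itself in the
# off-state (and a period boundary in the next pulse's on-state).
phase_decomp <- function(signal, t) {
  T <- signal$period
  tol <- 1e-9 * T
  i0 <- floor(t / T)
  phase <- t - i0 * T
  roll <- phase >= T - tol
  i0[roll] <- i0[roll] + 1
  phase[roll] <- 0
  on <- if (signal$duty_cycle == 1) rep(TRUE, length(t)) else
    phase < signal$pulse_on - tol
  list(pulse = as.integer(i0 + 1), phase = phase, on = on)
}

#' Time-averaged signal concentration
#'
#' The average of the square wave over one period, \eqn{\gamma A} — the
#' "average signal-molecule concentration" that titration curves are plotted
#' against.
#'
#' @inheritParams signal_at
#' @return A single concentration (nM).
#' @export
mean_signal <- function(signal) {
  stopifnot(inherits(signal, "square_wave"))
  signal$duty_cycle * signal$amplitude
}

#' Pulse index and phase
#'
#' Decompose times into the 1-based pulse index \eqn{i = \lfloor t/T\rfloor + 1}
#' and the phase \eqn{\xi_i = t - (i-1)T \in [0, T)} elapsed since the start
#' of that pulse.  A period boundary opens a new pulse.
#'
#' @inheritParams signal_at
#' @return A tibble with columns `time`, `pulse` (integer) and `phase` (h).
#' @examples
#' pulse_phase(square_wave(10, 6, 0.3), c(0, 5.9, 6, 13))
#' @export
pulse_phase <- function(signal, t) {
  stopifnot(inherits(signal, "square_wave"))
  if (any(t < 0)) ph_abort("`t` must be non-negative.")
  pd <- phase_decomp(signal, t)
  tibble(time = t, pulse = pd$pulse, phase = pd$phase)
}
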