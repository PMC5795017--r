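# Closed-form solution of the forced binding equation under square-wave
# forcing.  All exponentials are arranged as exp(x) with x <= 0 so the
# expressions stay finite over the full parameter range (k2*T from ~1e-4 to
# ~1e3); 1 - exp(-q) is always computed as -expm1(-q).

#' Sustained-signaling asymptote
#'
#' The binding probability reached at infinite time under a constant signal
#' of concentration `A`:
#' \deqn{\bar P_{sus} = \frac{A^n}{K_A^n + A^n}.}
#'
#' @inheritParams binding_rate
#' @param A Signal concentration (nM), `>= 0`; vectorized.
#' @return Binding probabilities in `[0, 1]`; 0 when `A = 0`.
#' @examples
#' p <- hill_params(n = 2, k1 = 0.01, K_A = 32)
#' sustained_binding(p, A = c(10, 20, 40))
#' @export
sustained_binding <- function(params, A) {
  stopifnot(inherits(params, "hill_params"))
  if (any(A < 0)) ph_abort("`A` must be non-negative.")
  ifelse(A > 0, 1 / (1 + (params$K_A / A)^params$n), 0)
}

# internal: shared pieces of the piecewise solution
solution_terms <- function(params, signal) {
  a <- params$k1 * signal$amplitude^params$n   # on-rate contribution k1*A^n
  k2 <- params$k2
  Delta <- signal$pulse_on
  T <- signal$period
  q <- a * Delta + k2 * T                      # per-period decay exponent
  list(
    a = a, k2 = k2, r = a + k2, Delta = Delta, T = T, q = q,
    D = -expm1(-q),                            # 1 - e^{-q}
    Psus = sustained_binding(params, signal$amplitude)
  )
}

#' Exact piecewise analytical binding probability
#'
#' Evaluates the closed-form solution of the forced binding equation for a
#' receptor that starts unbound at `t = 0`.  Within pulse `i`, writing
#' \eqn{\xi_i} for the phase and \eqn{\Delta} for the pulse-on time, the
#' rising branch (\eqn{0 \le \xi_i < \Delta}) is
#' \deqn{\frac{P_i(\xi_i)}{\bar P_{sus}} = 1 -
#'   \frac{e^{-\xi_i(k_1A^n+k_2)}}{1 - e^{-(k_1A^n\Delta + k_2T)}}
#'   \left[(1 - e^{k_2\Delta - k_2T}) +
#'   e^{-i(k_1A^n\Delta+k_2T)}(e^{(k_1A^n+k_2)\Delta} - 1)\right]}
#' and the falling branch (\eqn{\Delta \le \xi_i < T}) is
#' \deqn{\frac{P_i(\xi_i)}{\bar P_{sus}} =
#'   \frac{(e^{k_2\Delta} - e^{-k_1A^n\Delta})
#'         (1 - e^{-i(k_1A^n\Delta+k_2T)})}{1 - e^{-(k_1A^n\Delta+k_2T)}}
#'   e^{-k_2\xi_i}.}
#' The two branches join continuously at \eqn{\xi_i = \Delta} and across
#' period boundaries, and \eqn{P_1(0) = 0}.  For `duty_cycle = 1` the
#' sustained closed form
#' \eqn{P(t) = \bar P_{sus}(1 - e^{-(k_1A^n+k_2)t})} is used.
#'
#' @inheritParams simulate_binding
#' @param t Vector of times (h), `>= 0`.
#' @return Binding probabilities, same length as `t`.
#' @examples
#' p <- hill_params(n = 2, k1 = 0.01, K_A = 8)
#' sw <- square_wave(10, 6, 0.3)
#' analytic_binding(p, sw, c(0.5, 1.8, 3, 5.9, 7.3))
#' @export
analytic_binding <- function(params, signal, t) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  if (any(t < 0)) ph_abort("`t` must be non-negative.")
  if (signal$duty_cycle == 1) {
    r <- params$k1 * signal$amplitude^params$n + params$k2
    return(sustained_binding(params, signal$amplitude) * (-expm1(-r * t)))
  }
  tm <- solution_terms(params, signal)
  if (tm$Psus == 0) return(rep(0, length(t)))
  pd <- phase_decomp(signal, t)
  i <- pd$pulse
  xi <- pd$phase
  P <- numeric(length(t))
  rising <- pd$on  # same snapped edge convention as the numerical forcing
  if (any(rising)) {
    P[rising] <- rising_branch(tm, i[rising], xi[rising])
  }
  if (any(!rising)) {
    P[!rising] <- falling_branch(tm, i[!rising], xi[!rising])
  }
  if (any(!is.finite(P))) {
    abort("Analytical solution evaluated to a non-finite value.",
          class = "pulsehill_numeric_error")
  }
  P
}

# internal: rising branch of the piecewise solution, rearranged so that the
# transient bracket cancels exactly at i = 1 (P_1(xi) = Psus (1 - e^{-r xi}))
# and every exponential has a non-positive exponent:
#   P_i(xi)/Psus = (1 - e^{-r xi})
#     + e^{-r xi} [(e^{rD-q} - e^{-q}) - (e^{rD-iq} - e^{-iq})]/D
rising_branch <- function(tm, i, xi) {
  # exponents reduced algebraically (rD - q = k2(D - T), etc.) so no large
  # intermediate sums are subtracted
  e1 <- exp(tm$k2 * (tm$Delta - tm$T)) - exp(-tm$q)
  e2 <- exp(-(i - 1) * tm$a * tm$Delta + tm$k2 * (tm$Delta - i * tm$T)) -
    exp(-i * tm$q)
  tm$Psus * ((-expm1(-tm$r * xi)) + exp(-tm$r * xi) * (e1 - e2) / tm$D)
}

# internal: falling branch, equivalent to
#   (e^{k2 D} - e^{-a D}) (1 - e^{-iq}) e^{-k2 xi} / D
falling_branch <- function(tm, i, xi) {
  amp <- (exp(tm$k2 * (tm$Delta - xi)) -
            exp(-tm$a * tm$Delta - tm$k2 * xi)) / tm$D
  tm$Psus * amp * (-expm1(-i * tm$q))
}

# internal (used by the invariants tests): both branch values at pulse i,
# phase xi, regardless of which side of the pulse edge xi falls on
branch_values <- function(params, signal, i, xi) {
  tm <- solution_terms(params, signal)
  list(rising = rising_branch(tm, i, xi), falling = falling_branch(tm, i, xi))
}

#' Analytical trajectory on a regular grid
#'
#' Convenience wrapper around [analytic_binding()] producing the same kind of
#' `ph_trajectory` tibble as [simulate_binding()] (samples at multiples of
#' `dt_out` plus all pulse edges).
#'
#' @inheritParams simulate_binding
#' @return A `ph_trajectory` tibble with columns `time`, `signal`, `P`.
#' @export
analytic_trajectory <- function(params, signal, t_end,
                                dt_out = signal$period / 200) {
  check_number(t_end, "t_end", lower = 0, allow_lower = FALSE)
  tt <- build_time_grid(signal, t_end, dt_out)
  P <- analytic_binding(params, signal, tt)
  new_trajectory(tt, signal_at(signal, tt), pmin(1, pmax(0, P)),
                 params, signal, "analytic")
}

#' Limiting periodic cycle
#'
#' One period of the \eqn{i \to \infty} periodic orbit of the forced binding
#' equation (the transient terms \eqn{e^{-i(k_1A^n\Delta + k_2T)}} dropped),
#' sampled at `m_phase_points` phases plus the pulse-off edge.
#'
#' @inheritParams simulate_binding
#' @param m_phase_points Number of phase samples over `[0, period)`, `>= 2`.
#' @return A tibble with columns `phase` (h), `signal` (nM) and `P`.
#' @export
asymptotic_cycle <- function(params, signal, m_phase_points = 201) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  if (m_phase_points < 2) ph_abort("`m_phase_points` must be >= 2.")
  T <- signal$period
  xi <- seq(0, T, length.out = m_phase_points + 1L)[-(m_phase_points + 1L)]
  if (signal$duty_cycle < 1) {
    xi <- sort(unique(c(xi, signal$pulse_on)))
  }
  P <- asymptotic_cycle_at(params, signal, xi)
  tibble(phase = xi, signal = signal_at(signal, xi), P = P)
}

# internal: limiting-cycle P at phases xi in [0, T)
asymptotic_cycle_at <- function(params, signal, xi) {
  if (signal$duty_cycle == 1) {
    return(rep(sustained_binding(params, signal$amplitude), length(xi)))
  }
  tm <- solution_terms(params, signal)
  if (tm$Psus == 0) return(rep(0, length(xi)))
  Cr <- (-expm1(tm$k2 * (tm$Delta - tm$T))) / tm$D
  ifelse(
    phase_decomp(signal, xi)$on,
    tm$Psus * (1 - Cr * exp(-tm$r * xi)),
    tm$Psus * (exp(tm$k2 * (tm$Delta - xi)) -
                 exp(-tm$a * tm$Delta - tm$k2 * xi)) / tm$D
  )
}

#' Period-averaged binding at infinite time
#'
#' The exact time-average \eqn{\bar P_{pulsed}} of the limiting periodic
#' cycle over one period, obtained by closed-form integration of the two
#' exponential branches (no simulation, no truncation error).  In the slow
#' pulsing limit this tends to \eqn{\gamma \bar P_{sus}}, and in the fast
#' pulsing limit to \eqn{\gamma A^n / (K_A^n + \gamma A^n)}.
#'
#' @inheritParams simulate_binding
#' @return A single probability.
#' @examples
#' p <- hill_params(n = 2, k1 = 0.01, K_A = 8)
#' mean_pulsed_binding(p, square_wave(10, 6, 0.3))
#' @export
mean_pulsed_binding <- function(params, signal) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  Psus <- sustained_binding(params, signal$amplitude)
  if (signal$duty_cycle == 1 || Psus == 0) return(Psus)
  tm <- solution_terms(params, signal)
  Cr <- (-expm1(tm$k2 * (tm$Delta - tm$T))) / tm$D
  I_on <- tm$Delta - Cr * (-expm1(-tm$r * tm$Delta)) / tm$r
  if (tm$k2 == 0) {
    I_off <- tm$T - tm$Delta          # no unbinding: off-phase holds level 1
  } else {
    num <- (-expm1(tm$k2 * (tm$Delta - tm$T))) +
      (exp(-tm$a * tm$Delta - tm$k2 * tm$T) - exp(-tm$r * tm$Delta))
    I_off <- num / (tm$k2 * tm$D)
  }
  Psus * (I_on + I_off) / tm$T
}
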