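# Pulsing-regime classification: slow (d), competitive (e) and fast (f)
# pulsing from the dimensionless speed x = k2 (1 - gamma) T, the graded
# clocking sub-regime (g), rise times and the pulsing-delay boundary.

#' Rise time under sustained signaling
#'
#' Characteristic exponential-relaxation time of the bound fraction toward
#' its sustained asymptote, \eqn{\tau_{sus} = 1/(k_1 A^n + k_2) =
#' 1/(k_1(A^n + K_A^n))}.  Unbounded (`Inf`) if `A = 0` and `k2 = 0`.
#'
#' @inheritParams sustained_binding
#' @return Time (h).
#' @export
rise_time_sustained <- function(params, A) {
  stopifnot(inherits(params, "hill_params"))
  check_number(A, "A", lower = 0)
  r <- params$k1 * A^params$n + params$k2
  if (r == 0) Inf else 1 / r
}

#' Rise time under fast pulsing
#'
#' Rise time of the pulse-averaged bound fraction in the fast-pulsing
#' regime,
#' \deqn{\tau_{pulsed} = \frac{1}{k_1(A^n\gamma + K_A^n)} -
#'       \frac{T}{2}(1 - \gamma).}
#' The formula is only meaningful in regime f; outside its validity domain
#' it can be negative and is returned as-is, with the attribute `valid`
#' (`TRUE` when positive) flagging usability.  At `duty_cycle = 1` it
#' reduces exactly to [rise_time_sustained()].
#'
#' @inheritParams simulate_binding
#' @return Time (h) with attribute `valid`.
#' @export
rise_time_pulsed <- function(params, signal) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  g <- signal$duty_cycle
  tau <- 1 / (params$k1 * (signal$amplitude^params$n * g + params$K_d)) -
    (signal$period / 2) * (1 - g)
  structure(tau, valid = tau > 0)
}

#' Pulsing-delay factor
#'
#' Factor by which fast pulsing stretches the rise time when binding is
#' significantly delayed (small-period limit):
#' \deqn{\tau_{pulsed}/\tau_{sus} = \frac{A^n + K_A^n}{A^n\gamma + K_A^n}
#'       \;\to\; 1 + A^n/K_A^n \ \mathrm{as}\ \gamma \to 0.}
#'
#' @inheritParams simulate_binding
#' @return A dimensionless ratio `>= 1`.
#' @export
delay_factor <- function(params, signal) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  An <- signal$amplitude^params$n
  (An + params$K_d) / (An * signal$duty_cycle + params$K_d)
}

#' Largest dissociation constant at which pulsing delays binding
#'
#' The boundary value of \eqn{K_A} below which pulsed signaling takes longer
#' than sustained signaling to reach its asymptote
#' (\eqn{\tau_{pulsed} > \tau_{sus}}):
#' \deqn{K_A < \frac{A}{2^{1/n}}
#'  \left\{\left[(1-\gamma)^2 + \frac{8}{k_1TA^n}\right]^{1/2}
#'   - (1+\gamma)\right\}^{1/n},}
#' the closed-form root of the quadratic (in \eqn{K_A^n}) obtained by
#' equating the two rise times.  When the braced quantity is not positive no
#' real boundary exists — binding is never significantly delayed — and `NA`
#' is returned.
#'
#' @inheritParams simulate_binding
#' @return Concentration (nM) or `NA`.
#' @export
delay_boundary <- function(params, signal) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  g <- signal$duty_cycle
  if (g >= 1) ph_abort("`delay_boundary` requires duty_cycle < 1.")
  A <- signal$amplitude
  n <- params$n
  braced <- sqrt((1 - g)^2 + 8 / (params$k1 * signal$period * A^n)) - (1 + g)
  if (braced <= 0) return(NA_real_)
  A * (braced / 2)^(1 / n)
}

# internal: largest K_A in the fast-pulsing regime (where the within-period
# ripple becomes small): solves k1 K_A^n (1 - gamma) T = 1
fast_boundary_KA <- function(n, k1, duty_cycle, period) {
  (1 / (k1 * (1 - duty_cycle) * period))^(1 / n)
}

# internal: largest K_A in the graded-clocking regime with "<<" read as a
# factor eps: k2 T <= eps (1 - k1 A^n gamma T), requiring k1 A^n gamma T <= eps
graded_boundary_KA <- function(n, k1, A, duty_cycle, period, eps = 0.1) {
  if (k1 * A^n * duty_cycle * period > eps) return(NA_real_)
  rhs <- eps * (1 / (k1 * period) - duty_cycle * A^n)
  if (rhs <= 0) return(NA_real_)
  rhs^(1 / n)
}

#' Classify the pulsing regime
#'
#' Computes the dimensionless pulsing-speed parameter
#' \eqn{x = k_2(1-\gamma)T} and classifies: `slow_d` when `x >= threshold`
#' (binding relaxes fully within each pulse and tracks the signal),
#' `fast_f` when `x <= 1/threshold` (binding barely ripples within a period
#' and responds to the average drive), `competitive_e` in between.  The
#' qualitative "much greater / much less" is operationalized with a
#' symmetric factor (`threshold`, default 10).  The graded-clocking flag,
#' rise times and the boundary \eqn{K_A} values (fast, delay, graded) are
#' populated alongside.  `duty_cycle = 1` returns the distinct status
#' `"sustained"` — pulsing classification does not apply.
#'
#' @inheritParams simulate_binding
#' @param threshold Classification factor, `> 1` (default 10).
#' @param eps Factor reading of "much less than" for the graded-clocking
#'   conditions (default 0.1).
#' @return An object of class `regime_report`: a list with elements
#'   `regime`, `graded`, `x`, `tau_sus`, `tau_pulsed`, `tau_pulsed_valid`,
#'   `delay_factor`, `fast_boundary_K_A`, `delay_boundary_K_A`,
#'   `graded_boundary_K_A`, `threshold`, `eps`, plus the inputs.  Use
#'   [glance()] / [tidy()] for tibble views.
#' @examples
#' p <- hill_params(n = 2, k1 = 0.01, K_A = 32)
#' classify_regime(p, square_wave(40, 6, 0.3))
#' @export
classify_regime <- function(params, signal, threshold = 10, eps = 0.1) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  check_number(threshold, "threshold", lower = 1, allow_lower = FALSE)
  g <- signal$duty_cycle
  A <- signal$amplitude
  if (g == 1) {
    rep <- list(
      regime = "sustained", graded = NA, x = NA_real_,
      tau_sus = rise_time_sustained(params, A),
      tau_pulsed = NA_real_, tau_pulsed_valid = NA,
      delay_factor = 1,
      fast_boundary_K_A = NA_real_, delay_boundary_K_A = NA_real_,
      graded_boundary_K_A = NA_real_,
      threshold = threshold, eps = eps, params = params, signal = signal
    )
    return(structure(rep, class = "regime_report"))
  }
  x <- params$k2 * (1 - g) * signal$period
  regime <- if (x >= threshold) "slow_d"
    else if (x <= 1 / threshold) "fast_f"
    else "competitive_e"
  gc <- graded_conditions(params, signal, eps)
  tau_p <- rise_time_pulsed(params, signal)
  rep <- list(
    regime = regime, graded = gc$satisfied, x = x,
    tau_sus = rise_time_sustained(params, A),
    tau_pulsed = as.numeric(tau_p), tau_pulsed_valid = attr(tau_p, "valid"),
    delay_factor = delay_factor(params, signal),
    fast_boundary_K_A = fast_boundary_KA(params$n, params$k1, g,
                                         signal$period),
    delay_boundary_K_A = delay_boundary(params, signal),
    graded_boundary_K_A = graded_boundary_KA(params$n, params$k1, A, g,
                                             signal$period, eps),
    threshold = threshold, eps = eps, params = params, signal = signal
  )
  structure(rep, class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>\n")
  if (x$regime == "sustained") {
    cat("  sustained signaling (duty cycle 1); pulsing regimes not applicable\n")
  } else {
    cat(sprintf("  regime: %s  (x = k2(1-gamma)T = %.4g, threshold %g)\n",
                x$regime, x$x, x$threshold))
    cat(sprintf("  graded clocking: %s\n", x$graded))
  }
  cat(sprintf("  tau_sus = %.4g h; tau_pulsed = %.4g h (valid: %s)\n",
              x$tau_sus, x$tau_pulsed, x$tau_pulsed_valid))
  cat(sprintf("  boundaries K_A (nM): fast %.4g, delay %.4g, graded %.4g\n",
              x$fast_boundary_K_A, x$delay_boundary_K_A,
              x$graded_boundary_K_A))
  invisible(x)
}

# internal: the two graded-clocking inequalities with "<<" read as eps
graded_conditions <- function(params, signal, eps = 0.1) {
  g <- signal$duty_cycle
  drive <- params$k1 * signal$amplitude^params$n * g * signal$period
  cond_drive <- drive <= eps
  cond_k2 <- params$k2 * signal$period <= eps * (1 - drive)
  list(satisfied = cond_drive && cond_k2,
       drive = drive, cond_drive = cond_drive, cond_k2 = cond_k2)
}

#' Graded clocking: per-pulse binding levels
#'
#' In the graded-clocking sub-regime of fast pulsing, the bound level is
#' essentially flat within each period but steps up with every pulse, and
#' initially the level after pulse \eqn{i} is simply proportional to the
#' number of pulses received: \eqn{P_i(T) \approx i\,P_1(T)}.  The regime
#' requires both \eqn{k_2 T \ll 1 - k_1 A^n \gamma T} and
#' \eqn{k_1 A^n \gamma T \ll 1}, with "much less" read as the factor `eps`.
#' Linearity is measured over the initial window
#' \eqn{i \le 0.1\,\bar P_{pulsed}/P_1(T)} (where the geometric approach to
#' the asymptote is still close to linear).
#'
#' @inheritParams classify_regime
#' @param i_max Number of pulses to evaluate, `>= 3`.
#' @return A list with `satisfied` (logical), `levels` (tibble with columns
#'   `pulse` and `P_end`, the analytic end-of-period levels \eqn{P_i(T)}),
#'   and `linearity_error` (max relative deviation of \eqn{P_i(T)} from
#'   \eqn{i P_1(T)} over the linear window).
#' @examples
#' p <- hill_params(n = 2, k1 = 0.01, K_A = 1)
#' graded_clocking(p, square_wave(40, 0.06, 0.1), i_max = 20)
#' @export
graded_clocking <- function(params, signal, i_max = 50, eps = 0.1) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  if (i_max < 3) ph_abort("`i_max` must be >= 3.")
  if (signal$duty_cycle >= 1) ph_abort("graded clocking requires duty_cycle < 1.")
  gc <- graded_conditions(params, signal, eps)
  tm <- solution_terms(params, signal)
  i <- seq_len(i_max)
  # falling branch of the analytic solution at xi = T (end of period i)
  amp <- (exp(tm$k2 * (tm$Delta - tm$T)) -
            exp(-tm$a * tm$Delta - tm$k2 * tm$T)) / tm$D
  P_end <- tm$Psus * amp * (-expm1(-i * tm$q))
  P1 <- P_end[1]
  Pbar <- mean_pulsed_binding(params, signal)
  i_win <- max(1L, min(i_max, floor(0.1 * Pbar / P1)))
  lin_err <- max(abs(P_end[1:i_win] / (seq_len(i_win) * P1) - 1))
  list(
    satisfied = gc$satisfied,
    levels = tibble(pulse = i, P_end = P_end),
    linearity_error = lin_err,
    linear_window = i_win,
    conditions = gc[c("drive", "cond_drive", "cond_k2")]
  )
}

#' Regime membership along a dissociation-constant grid
#'
#' Sweeps \eqn{K_A} with all other parameters fixed (so
#' \eqn{k_2 = k_1 K_A^n} varies along the grid), classifying the pulsing
#' regime at each value and marking where the three characteristic
#' boundaries fall: the fast-pulsing boundary (\eqn{k_2(1-\gamma)T = 1}),
#' the pulsing-delay boundary, and the graded-clocking boundary.  These are
#' the dashed overlay lines of the classic heatmap view.  With
#' `duty_cycle = 1` every row is `"sustained"` and no boundaries exist.
#'
#' @inheritParams titration_curve
#' @param k1 Association rate constant (nM^-n h^-1).
#' @param A Pulse amplitude (nM).
#' @param K_A Increasing positive grid of dissociation constants (nM).
#' @param threshold,eps As in [classify_regime()].
#' @return A tibble with one row per `K_A`: columns `K_A`, `k2`, `x`,
#'   `regime`, `graded`, `delayed`, and logical marks `is_fast_boundary`,
#'   `is_delay_boundary`, `is_graded_boundary` (set on the largest grid
#'   value still inside the respective region).  The exact boundary
#'   concentrations are attached as the attribute `boundaries`.
#' @export
regime_boundaries <- function(n, k1, A, duty_cycle, period,
                              K_A = 2^seq(0, 6, length.out = 64),
                              threshold = 10, eps = 0.1) {
  if (any(diff(K_A) <= 0) || any(K_A <= 0)) {
    ph_abort("`K_A` must be positive and strictly increasing.")
  }
  g <- duty_cycle
  if (g == 1) {
    out <- tibble(
      K_A = K_A, k2 = k1 * K_A^n, x = NA_real_, regime = "sustained",
      graded = NA, delayed = NA,
      is_fast_boundary = FALSE, is_delay_boundary = FALSE,
      is_graded_boundary = FALSE
    )
    attr(out, "boundaries") <-
      c(fast = NA_real_, delay = NA_real_, graded = NA_real_)
    return(out)
  }
  sig <- square_wave(A, period, g)
  k2 <- k1 * K_A^n
  x <- k2 * (1 - g) * period
  regime <- ifelse(x >= threshold, "slow_d",
                   ifelse(x <= 1 / threshold, "fast_f", "competitive_e"))
  p0 <- hill_params(n = n, k1 = k1, K_A = K_A[1])
  b_fast <- fast_boundary_KA(n, k1, g, period)
  b_delay <- delay_boundary(p0, sig)       # independent of K_A
  b_graded <- graded_boundary_KA(n, k1, A, g, period, eps)
  graded <- vapply(K_A, function(K) {
    graded_conditions(hill_params(n = n, k1 = k1, K_A = K), sig,
                      eps)$satisfied
  }, logical(1))
  delayed <- if (is.na(b_delay)) rep(FALSE, length(K_A)) else K_A < b_delay
  mark_last <- function(b) {
    m <- rep(FALSE, length(K_A))
    if (!is.na(b) && any(K_A <= b)) m[max(which(K_A <= b))] <- TRUE
    m
  }
  out <- tibble(
    K_A = K_A, k2 = k2, x = x, regime = regime, graded = graded,
    delayed = delayed,
    is_fast_boundary = mark_last(b_fast),
    is_delay_boundary = mark_last(b_delay),
    is_graded_boundary = mark_last(b_graded)
  )
  attr(out, "boundaries") <- c(fast = b_fast, delay = b_delay,
                               graded = b_graded)
  out
}
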