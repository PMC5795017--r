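# Closed-form limiting-case quantities: suppression ratios, the apparent
# dissociation-constant shift, matched-mean and cumulative-exposure ratios,
# and titration curves.

#' Low-affinity sensitivity approximation
#'
#' For low-affinity receptors (\eqn{K_A^n \gg A^n}) the sustained asymptote
#' reduces to the power law \eqn{\bar P_{sus} \approx (A/K_A)^n}, which makes
#' the binding extremely sensitive to the signal concentration.  Valid only
#' in that limit; compare with [sustained_binding()] for the exact value.
#'
#' @inheritParams sustained_binding
#' @return `(A/K_A)^n` (vectorized over `A`).
#' @export
low_affinity_sensitivity <- function(params, A) {
  stopifnot(inherits(params, "hill_params"))
  if (any(A < 0)) ph_abort("`A` must be non-negative.")
  (A / params$K_A)^params$n
}

#' Pulsed-to-sustained suppression ratio in the limiting regimes
#'
#' The ratio \eqn{\bar P_{pulsed}/\bar P_{sus}} in the two limits:
#' slow pulsing gives exactly the duty cycle \eqn{\gamma}; fast pulsing gives
#' \deqn{\gamma\,\frac{K_A^n + A^n}{K_A^n + \gamma A^n},}
#' which tends to 1 for high-affinity receptors (small \eqn{K_A}) and to
#' \eqn{\gamma} for low-affinity ones.  These are limits chosen explicitly by
#' the caller; the general-case number is `mean_pulsed_binding(...) /
#' sustained_binding(...)`.
#'
#' @inheritParams simulate_binding
#' @param regime `"slow"` or `"fast"`.
#' @return A dimensionless ratio in `(0, 1]`.
#' @examples
#' p <- hill_params(n = 2, k1 = 0.01, K_A = 10)
#' suppression_ratio(p, square_wave(10, 6, 0.3), "fast")
#' @export
suppression_ratio <- function(params, signal, regime = c("slow", "fast")) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  regime <- match.arg(regime)
  g <- signal$duty_cycle
  if (regime == "slow") return(g)
  Kn <- params$K_A^params$n
  An <- signal$amplitude^params$n
  g * (Kn + An) / (Kn + g * An)
}

#' Apparent dissociation-constant shift
#'
#' Under fast pulsing the titration curve against the *average* signal
#' concentration looks like a Hill curve with a reduced, apparent
#' dissociation constant \eqn{K'_A}.  The reduction factor is
#' \deqn{K'_A / K_A = \gamma^{(n-1)/n},}
#' e.g. \eqn{0.3^{1/2} = 0.55} for `n = 2` and \eqn{0.3^{3/4} = 0.41} for
#' `n = 4` at duty cycle 0.3.
#'
#' @param duty_cycle Duty cycle in `(0, 1]`.
#' @param n Hill coefficient, `>= 1`.
#' @return The dimensionless ratio \eqn{K'_A/K_A}.
#' @examples
#' apparent_KA_ratio(0.3, 2)
#' apparent_KA_ratio(0.3, 4)
#' @export
apparent_KA_ratio <- function(duty_cycle, n) {
  check_number(duty_cycle, "duty_cycle", lower = 0, upper = 1,
               allow_lower = FALSE)
  check_number(n, "n", lower = 1)
  duty_cycle^((n - 1) / n)
}

#' Sustained vs pulsed binding at matched mean signal
#'
#' Ratio of the sustained asymptote evaluated at the *average* pulsed
#' concentration \eqn{[S] = \gamma A} to the fast-pulsing average
#' \eqn{\bar P_{pulsed}}:
#' \deqn{\gamma^{\,n-1}\,\frac{K_A^n + \gamma A^n}{K_A^n + \gamma^n A^n}.}
#' It approaches 1 as \eqn{\gamma \to 1} and falls to order
#' \eqn{\gamma^{n-1}} as \eqn{\gamma \to 0}: at equal average exposure,
#' pulsed delivery is the more effective way to drive cooperative binding.
#'
#' @inheritParams simulate_binding
#' @return A dimensionless ratio.
#' @export
matched_mean_ratio <- function(params, signal) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  g <- signal$duty_cycle
  n <- params$n
  Kn <- params$K_A^n
  An <- signal$amplitude^n
  g^(n - 1) * (Kn + g * An) / (Kn + g^n * An)
}

#' Cumulative product ratio at equal accumulated signal exposure
#'
#' Asymptotic ratio of accumulated product
#' \eqn{c^P(t') = \int_0^{t'} P\,dt} from sustained vs pulsed signaling,
#' compared at the (different) times giving the same accumulated signal
#' exposure \eqn{c^S = \int [S]\,dt} (for a square wave, \eqn{t'' = t'/\gamma}
#' for the pulsed run).  Slow pulsing gives 1 — only total signal delivered
#' matters; fast pulsing gives \eqn{(K_A^n + \gamma A^n)/(K_A^n + A^n)},
#' which tends to 1 for low affinity and to \eqn{\gamma} for high affinity.
#'
#' @inheritParams suppression_ratio
#' @return A dimensionless ratio in `(0, 1]`.
#' @export
cumulative_product_ratio <- function(params, signal,
                                     regime = c("slow", "fast")) {
  stopifnot(inherits(params, "hill_params"), inherits(signal, "square_wave"))
  regime <- match.arg(regime)
  if (regime == "slow") return(1)
  Kn <- params$K_A^params$n
  An <- signal$amplitude^params$n
  (Kn + signal$duty_cycle * An) / (Kn + An)
}

#' Accumulated product and signal exposure
#'
#' Adds running trapezoidal integrals of the bound fraction (`c_P`,
#' probability-hours) and of the signal concentration (`c_S`, nM h) to a
#' trajectory.  Pulse edges are already nodes of the trajectory grid, so the
#' trapezoid rule commits no error at the discontinuities of `[S]`.
#'
#' @param trajectory A `ph_trajectory` tibble from [simulate_binding()] or
#'   [analytic_trajectory()].
#' @return The trajectory with extra columns `c_P` and `c_S`.
#' @export
cumulative_exposure <- function(trajectory) {
  stopifnot(is.data.frame(trajectory),
            all(c("time", "signal", "P") %in% names(trajectory)))
  dplyr::mutate(
    trajectory,
    c_P = cumtrapz(.data$time, .data$P),
    c_S = cumtrapz(.data$time, .data$signal)
  )
}

#' Titration curve of average binding vs average signal
#'
#' Computes the infinite-time average binding probability as a function of
#' the average signal-molecule concentration \eqn{\bar{[S]} = \gamma A}, for
#' a fixed dimensionless pulsing speed `k2T` (so \eqn{k_2 = k_2T/T} and
#' \eqn{k_1 = k_2/K_A^n} with the reference period).  Each point is the
#' exact cycle average from [mean_pulsed_binding()]; `duty_cycle = 1`
#' reproduces the sustained Hill curve.  The half-saturation concentration —
#' the apparent dissociation constant \eqn{K'_A} — is located by monotone
#' root bracketing on the log concentration axis (relative tolerance 1e-6)
#' and reported as `NA` when the grid does not bracket binding 0.5.
#'
#' @param n Hill coefficient.
#' @param duty_cycle Duty cycle in `(0, 1]`.
#' @param k2T Dimensionless pulsing-speed parameter \eqn{k_2 T} (0.1 is deep
#'   in the fast-pulsing regime, 10 in the slow-pulsing regime at
#'   `duty_cycle` well below 1).
#' @param K_A Dissociation constant (nM); also sets the default grid.
#' @param mean_signal Optional increasing grid of average concentrations
#'   (nM); defaults to 60 log-spaced points over `[0.01, 100] * K_A`.
#' @param period Reference pulsing period (h), default 6.
#'
#' @return A `ph_titration` tibble with columns `mean_signal` and
#'   `mean_binding`, and attributes `half_saturation` (nM), `shift`
#'   (`half_saturation / K_A`), `n`, `duty_cycle`, `k2T` and `K_A`.
#'   [glance()] returns these as a one-row tibble.
#'
#' @examples
#' tc <- titration_curve(n = 2, duty_cycle = 0.3, k2T = 0.1, K_A = 10)
#' glance(tc)
#' @export
titration_curve <- function(n, duty_cycle, k2T, K_A = 10,
                            mean_signal = NULL, period = 6) {
  check_number(n, "n", lower = 1)
  check_number(duty_cycle, "duty_cycle", lower = 0, upper = 1,
               allow_lower = FALSE)
  check_number(k2T, "k2T", lower = 0, allow_lower = FALSE)
  check_number(K_A, "K_A", lower = 0, allow_lower = FALSE)
  if (is.null(mean_signal)) {
    mean_signal <- K_A * 10^seq(-2, 2, length.out = 60)
  }
  if (any(diff(mean_signal) <= 0) || any(mean_signal <= 0)) {
    ph_abort("`mean_signal` must be positive and strictly increasing.")
  }
  k2 <- k2T / period
  k1 <- k2 / K_A^n
  params <- hill_params(n = n, k1 = k1, K_A = K_A)
  mb_at <- function(S) {
    mean_pulsed_binding(params, square_wave(S / duty_cycle, period,
                                            duty_cycle))
  }
  mean_binding <- vapply(mean_signal, mb_at, numeric(1))

  half <- NA_real_
  if (min(mean_binding) < 0.5 && max(mean_binding) > 0.5) {
    lo <- log(mean_signal[1]); hi <- log(mean_signal[length(mean_signal)])
    half <- exp(uniroot(function(ls) mb_at(exp(ls)) - 0.5, c(lo, hi),
                        tol = 1e-6 / 2)$root)
  }
  new_tibble(
    tibble(mean_signal = mean_signal, mean_binding = mean_binding),
    half_saturation = half, shift = half / K_A,
    n = n, duty_cycle = duty_cycle, k2T = k2T, K_A = K_A, period = period,
    class = "ph_titration"
  )
}
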