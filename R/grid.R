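# Heatmap-style scenario grids: P(t; K_A) over a log-spaced range of
# dissociation constants with all other parameters fixed, plus the registry
# of the standard panel parameter combinations.

#' Binding-probability grid over a range of dissociation constants
#'
#' Evaluates \eqn{P(t; K_A)} on a log-spaced grid of dissociation constants
#' (default 64 points over 1-64 nM) and a time grid resolving each pulse,
#' using the analytic solution (or the numerical integrator on request, for
#' cross-checking).  The three regime boundary concentrations
#' (fast-pulsing, delay, graded clocking) are attached for overlay.
#'
#' @inheritParams regime_boundaries
#' @param t_end End time (h), default four periods.
#' @param points_per_period Regular time samples per period (default 200).
#' @param method `"analytic"` or `"numeric"` (exact per-segment integrator).
#' @return A `ph_grid` tibble in long format with columns `K_A`, `time`,
#'   `signal` and `P`, attributes `boundaries` (named numeric) and `banner`
#'   (the fixed parameters).  Plot with [autoplot()].
#' @examples
#' g <- scenario_grid(n = 2, k1 = 0.01, A = 40, duty_cycle = 0.3,
#'                    K_A = 2^seq(0, 6), points_per_period = 60)
#' dplyr::count(g, K_A)
#' @export
scenario_grid <- function(n, k1, A, duty_cycle, period = 6,
                          K_A = 2^seq(0, 6, length.out = 64),
                          t_end = 4 * period, points_per_period = 200,
                          method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (any(diff(K_A) <= 0) || any(K_A <= 0)) {
    ph_abort("`K_A` must be positive and strictly increasing.")
  }
  sig <- square_wave(A, period, duty_cycle)
  tt <- build_time_grid(sig, t_end, period / points_per_period)
  sv <- signal_at(sig, tt)
  rows <- purrr::map_dfr(K_A, function(K) {
    p <- hill_params(n = n, k1 = k1, K_A = K)
    P <- switch(method,
      analytic = pmin(1, pmax(0, analytic_binding(p, sig, tt))),
      numeric = simulate_binding(p, sig, t_end = t_end,
                                 dt_out = period / points_per_period)$P
    )
    tibble(K_A = K, time = tt, signal = sv, P = P)
  })
  bounds <- attr(
    regime_boundaries(n, k1, A, duty_cycle, period, K_A = K_A),
    "boundaries"
  )
  new_tibble(
    rows,
    boundaries = bounds,
    banner = list(n = n, k1 = k1, A = A, duty_cycle = duty_cycle,
                  period = period, method = method),
    class = "ph_grid"
  )
}

#' Registry of the standard scenario panels
#'
#' The canonical 20-panel parameter set for the heatmap view: five
#' (amplitude, k1) rows crossed with duty cycles 1 (sustained), 0.8, 0.3 and
#' 0.1, at period 6 h and Hill coefficient 2.  The rows at
#' `k1 = 10e-3 nM^-2 h^-1` with A = 10, 20, 40 nM are fixed by the standard
#' description; the remaining two rows (`k1` = 0.1e-3 and 1e-3) are encoded
#' at A = 40 nM and flagged `inferred = TRUE`.
#'
#' @return A tibble with 20 rows and columns `panel`, `A`, `k1`,
#'   `duty_cycle`, `period`, `n`, `inferred`.
#' @export
scenario_panels <- function() {
  rows <- tibble(
    A = c(40, 40, 40, 20, 10),
    k1 = c(0.1e-3, 1e-3, 10e-3, 10e-3, 10e-3),
    inferred = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  out <- tidyr::crossing(rows, duty_cycle = c(1, 0.8, 0.3, 0.1))
  out <- dplyr::arrange(out, .data$k1, dplyr::desc(.data$A),
                        dplyr::desc(.data$duty_cycle))
  dplyr::mutate(out,
    panel = dplyr::row_number(), period = 6, n = 2,
    .before = 1
  )
}
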