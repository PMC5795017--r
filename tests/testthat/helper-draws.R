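# Random parameter draws spanning the study conditions: Hill coefficients 2
# and 4, log-uniform rate constants and affinities over the ranges of the
# reference scenario grids (K_A 1-64 nM, amplitudes up to 100 nM, period 6 h).
draw_cases <- function(n_draws, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    n = sample(c(2, 4), n_draws, replace = TRUE),
    k1 = 10^stats::runif(n_draws, -4, -1),
    K_A = 10^stats::runif(n_draws, 0, log10(64)),
    A = 10^stats::runif(n_draws, 0.3, 2),
    duty_cycle = stats::runif(n_draws, 0.05, 0.95),
    period = 6
  )
}

# draws pinned to a given pulsing speed x = k2 (1 - gamma) T, with k1
# derived from K_A so the affinity is unchanged
draw_cases_at_speed <- function(n_draws, x, seed = 1) {
  d <- draw_cases(n_draws, seed)
  d$duty_cycle <- stats::runif(n_draws, 0.1, 0.9)
  k2 <- x / ((1 - d$duty_cycle) * d$period)
  d$k1 <- k2 / d$K_A^d$n
  d
}

case_objects <- function(case) {
  list(
    params = hill_params(n = case$n, k1 = case$k1, K_A = case$K_A),
    signal = square_wave(case$A, case$period, case$duty_cycle)
  )
}
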