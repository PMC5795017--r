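test_that("pulsing speed x = k2(1-gamma)T classifies slow, competitive and fast", {
  sw <- square_wave(10, 6, 0.3)
  r1 <- classify_regime(hill_params(n = 2, k1 = 0.1, k2 = 10), sw)
  expect_equal(r1$regime, "slow_d")
  expect_equal(r1$x, 42)
  r2 <- classify_regime(hill_params(n = 2, k1 = 1e-5, k2 = 0.001), sw)
  expect_equal(r2$regime, "fast_f")
  r3 <- classify_regime(hill_params(n = 2, k1 = 0.01, k2 = 0.238), sw)
  expect_equal(r3$regime, "competitive_e")
  # sustained signaling is a distinct status, not a regime
  rs <- classify_regime(hill_params(n = 2, k1 = 0.01, K_A = 8),
                        square_wave(10, 6, 1))
  expect_equal(rs$regime, "sustained")
  expect_true(is.na(rs$x))
  gl <- glance(r1)
  expect_equal(gl$regime, "slow_d")
  expect_equal(nrow(tidy(r1)), 7)
})

test_that("regime label is invariant under joint rate/period rescaling", {
  cases <- draw_cases(30, seed = 13)
  for (j in seq_len(nrow(cases))) {
    cs <- cases[j, ]
    for (c_scale in c(0.1, 17)) {
      r_a <- classify_regime(
        hill_params(n = cs$n, k1 = cs$k1, K_A = cs$K_A),
        square_wave(cs$A, cs$period, cs$duty_cycle)
      )
      r_b <- classify_regime(
        hill_params(n = cs$n, k1 = c_scale * cs$k1, K_A = cs$K_A),
        square_wave(cs$A, cs$period / c_scale, cs$duty_cycle)
      )
      expect_equal(r_b$regime, r_a$regime)
    }
  }
})

test_that("sustained rise time is the inverse total relaxation rate", {
  p <- hill_params(n = 2, k1 = 0.01, K_A = 32)
  expect_equal(rise_time_sustained(p, 40), 1 / (0.01 * (1600 + 1024)))
  expect_equal(rise_time_sustained(p, 40), 0.0381, tolerance = 1e-3)
  expect_equal(rise_time_sustained(p, 0), 1 / p$k2)
  expect_equal(rise_time_sustained(hill_params(n = 2, k1 = 1, k2 = 0), 0),
               Inf)
  # numeric cross-check: time to reach (1 - 1/e) of the asymptote
  tr <- simulate_binding(p, square_wave(40, 6, 1), t_end = 0.4,
                         dt_out = 1e-4)
  target <- (1 - exp(-1)) * sustained_binding(p, 40)
  t_num <- tr$time[which(tr$P >= target)[1]]
  expect_equal(t_num, rise_time_sustained(p, 40), tolerance = 0.01)
})

test_that("pulsed rise time reduces to sustained at duty cycle 1 and carries a validity flag", {
  p <- hill_params(n = 2, k1 = 0.01, K_A = 8)
  expect_equal(as.numeric(rise_time_pulsed(p, square_wave(40, 6, 1))),
               rise_time_sustained(p, 40))
  tau <- rise_time_pulsed(p, square_wave(40, 0.1, 0.3))
  expect_equal(as.numeric(tau), 1 / (0.01 * (1600 * 0.3 + 64)) - 0.035)
  expect_equal(as.numeric(tau), 0.1488, tolerance = 1e-3)
  expect_true(attr(tau, "valid"))
  # negative outside the validity domain, flagged but returned as-is
  tau_bad <- rise_time_pulsed(p, square_wave(40, 40, 0.3))
  expect_lt(as.numeric(tau_bad), 0)
  expect_false(attr(tau_bad, "valid"))
})

test_that("pulse-averaged numeric rise time agrees with the fast-pulsing formula", {
  # fast pulsing (x = 0.045) with a real delay boundary
  p <- hill_params(n = 2, k1 = 0.01, K_A = 8)
  sw <- square_wave(40, 0.1, 0.3)
  tau <- as.numeric(rise_time_pulsed(p, sw))
  tr <- simulate_binding(p, sw, t_end = 60 * sw$period, dt_out = sw$period / 50)
  per <- floor(tr$time / sw$period)
  pa <- tapply(tr$P, per, mean)
  t_mid <- (as.numeric(names(pa)) + 0.5) * sw$period
  target <- (1 - exp(-1)) * mean_pulsed_binding(p, sw)
  i_hit <- which(pa >= target)[1]
  # linear interpolation between period midpoints
  t_num <- unname(t_mid[i_hit - 1] + (target - pa[i_hit - 1]) /
    (pa[i_hit] - pa[i_hit - 1]) * (t_mid[i_hit] - t_mid[i_hit - 1]))
  expect_equal(t_num, tau, tolerance = 0.1)
})

test_that("the delay boundary is exactly where pulsed and sustained rise times cross", {
  p <- hill_params(n = 2, k1 = 1e-3, K_A = 1)
  sw <- square_wave(10, 6, 0.1)
  b <- delay_boundary(p, sw)
  f <- function(K) {
    pp <- hill_params(n = 2, k1 = 1e-3, K_A = K)
    as.numeric(rise_time_pulsed(pp, sw)) - rise_time_sustained(pp, 10)
  }
  root <- uniroot(f, c(1e-3, 1e3), tol = 1e-12)$root
  expect_equal(b, root, tolerance = 1e-6)
  # below the boundary pulsing delays binding, above it does not
  expect_gt(f(b * 0.9), 0)
  expect_lt(f(b * 1.1), 0)
  # boundary shrinks as the duty cycle approaches sustained signaling
  bs <- vapply(c(0.1, 0.3, 0.8), function(g) {
    delay_boundary(p, square_wave(10, 6, g))
  }, numeric(1))
  expect_true(all(diff(bs) < 0))
  # no real boundary when the braced term is negative
  expect_true(is.na(delay_boundary(hill_params(n = 2, k1 = 0.01, K_A = 1),
                                   square_wave(40, 6, 0.3))))
})

test_that("delay factor interpolates between 1 and 1 + A^n/K_A^n", {
  p <- hill_params(n = 2, k1 = 0.01, K_A = 8)
  expect_equal(delay_factor(p, square_wave(40, 6, 1)), 1)
  # (A^n + K_A^n)/(A^n gamma + K_A^n) = (1600 + 64)/(480 + 64)
  expect_equal(delay_factor(p, square_wave(40, 6, 0.3)), 1664 / 544)
  pk <- hill_params(n = 2, k1 = 0.01, K_A = 10)
  expect_equal(delay_factor(pk, square_wave(10, 6, 1e-9)), 2,
               tolerance = 1e-6)
})

test_that("graded clocking gives near-linear per-pulse increments inside its conditions", {
  # marginal case, just inside the epsilon = 0.1 boundary: the condition is
  # satisfied and the first pulse is already a small fraction of the
  # asymptote, but the linear window holds only a single pulse
  A <- 40; g <- 0.1; T <- 6
  k1 <- 0.099 / (A^2 * g * T)
  k2 <- 0.089 / T
  p <- hill_params(n = 2, k1 = k1, k2 = k2)
  sw <- square_wave(A, T, g)
  gc <- graded_clocking(p, sw, i_max = 300)
  expect_true(gc$satisfied)
  expect_lte(gc$linearity_error, 0.1)
  expect_lte(gc$levels$P_end[1] / mean_pulsed_binding(p, sw), 0.2)
  # deep inside regime g (high affinity, short period): many pulses in the
  # linear window with near-constant positive increments
  pd <- hill_params(n = 2, k1 = 0.01, K_A = 1)
  sd <- square_wave(40, 0.01, 0.1)
  gd <- graded_clocking(pd, sd, i_max = 500)
  expect_true(gd$satisfied)
  expect_gt(gd$linear_window, 3)
  expect_lte(gd$linearity_error, 0.1)
  inc <- diff(gd$levels$P_end[1:gd$linear_window])
  expect_true(all(inc > 0))
  expect_lt(max(abs(inc / inc[1] - 1)), 0.1)
  # slow pulsing violates the conditions
  gs <- graded_clocking(hill_params(n = 2, k1 = 0.1, k2 = 10),
                        square_wave(10, 6, 0.3))
  expect_false(gs$satisfied)
})

test_that("regime membership along a K_A grid marks ordered boundaries", {
  rb <- regime_boundaries(n = 2, k1 = 0.01, A = 40, duty_cycle = 0.3,
                          period = 6)
  b <- attr(rb, "boundaries")
  # fast boundary solves k1 K_A^2 (1 - gamma) T = 1
  expect_equal(b[["fast"]], sqrt(1 / (0.01 * 0.7 * 6)))
  expect_equal(b[["fast"]], 4.88, tolerance = 1e-3)
  expect_true(all(rb$regime[rb$x <= 0.1] == "fast_f"))
  expect_true(all(rb$regime[rb$x >= 10] == "slow_d"))
  # graded region is strictly inside the fast region whenever both exist
  rb2 <- regime_boundaries(n = 2, k1 = 1e-4, A = 10, duty_cycle = 0.1,
                           period = 6)
  b2 <- attr(rb2, "boundaries")
  if (!is.na(b2[["graded"]]) && !is.na(b2[["fast"]])) {
    expect_lte(b2[["graded"]], b2[["fast"]])
  }
  expect_true(all(rb2$K_A[rb2$graded] <=
                    rb2$K_A[rb2$regime == "fast_f"] |> max()))
  # sustained column: no boundaries at all
  rb1 <- regime_boundaries(n = 2, k1 = 0.01, A = 40, duty_cycle = 1,
                           period = 6)
  expect_true(all(rb1$regime == "sustained"))
  expect_true(all(is.na(attr(rb1, "boundaries"))))
})

test_that("deep regimes behave as advertised: tracking in d, small ripple in f", {
  # x >= 100: cycle follows the signal
  pd <- hill_params(n = 2, k1 = 3, K_A = 3)   # k2 = 27, x = 113 at g = 0.3
  sd <- square_wave(10, 6, 0.3)
  cyc <- asymptotic_cycle(pd, sd, 600)
  Psus <- sustained_binding(pd, 10)
  on_end <- max(cyc$P[cyc$signal > 0])
  off_end <- min(cyc$P)
  expect_gte(on_end, 0.95 * Psus)
  expect_lte(off_end, 0.05 * Psus)
  # x <= 0.01: ripple below 5% of the mean
  pf <- hill_params(n = 2, k1 = 1e-5, K_A = 10)  # k2 = 1e-3, x = 0.0042
  cycf <- asymptotic_cycle(pf, sd, 600)
  Pbar <- mean_pulsed_binding(pf, sd)
  expect_lte((max(cycf$P) - min(cycf$P)) / Pbar, 0.05)
})
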