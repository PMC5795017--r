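# Dimerization-coupled promoter binding: p53 monomers equilibrate to dimers
# (dissociation constant K_Ad), and two dimers bind the promoter
# cooperatively (constant K_AR), so the DNA-binding step is a Hill reaction
# in the dimer with n = 2.  Dimerization is treated as instantaneously
# equilibrated (quasi-steady state), and p53 bound to DNA is neglected in
# the mass balance.

#' Equilibrium dimer concentration
#'
#' Solves the dimerization equilibrium
#' \eqn{K_{Ad} = [\mathrm{p53}]^2/[\mathrm{p53}_2]} together with the mass
#' balance \eqn{[\mathrm{p53}]_{total} = [\mathrm{p53}] + 2[\mathrm{p53}_2]}.
#' The closed-form root is evaluated in the cancellation-free conjugate form
#' \deqn{[\mathrm{p53}_2] = \frac{2\,[\mathrm{p53}]_{total}^2}
#'   {4[\mathrm{p53}]_{total} + K_{Ad} +
#'    \sqrt{K_{Ad}^2 + 8K_{Ad}[\mathrm{p53}]_{total}}},}
#' algebraically identical to
#' \eqn{8[\mathrm{p53}_2] = 4[\mathrm{p53}]_{total} + K_{Ad} -
#' (K_{Ad}^2 + 8K_{Ad}[\mathrm{p53}]_{total})^{1/2}} but accurate over many
#' orders of magnitude in \eqn{K_{Ad}/[\mathrm{p53}]_{total}}.
#'
#' @param K_Ad Dimerization dissociation constant (nM), `>= 0`.
#' @param p53_total Total p53 concentration (nM), `>= 0`.  Vectorized.
#' @return Dimer concentration (nM), in `[0, p53_total/2]`.
#' @examples
#' dimer_concentration(K_Ad = 8, p53_total = 4)
#' dimer_concentration(K_Ad = 0, p53_total = 20) # full dimerization
#' @export
dimer_concentration <- function(K_Ad, p53_total) {
  if (any(K_Ad < 0) || any(p53_total < 0)) {
    ph_abort("`K_Ad` and `p53_total` must be non-negative.")
  }
  ifelse(
    p53_total > 0,
    2 * p53_total^2 /
      (4 * p53_total + K_Ad + sqrt(K_Ad^2 + 8 * K_Ad * p53_total)),
    0
  )
}

#' Dimerization-coupled binding system
#'
#' Bundle of the p53 dimerization and promoter-binding parameters.  The
#' dimer concentration is derived on construction and the mass balance is
#' verified.
#'
#' @param K_Ad Dimerization dissociation constant (nM).
#' @param K_AR Promoter-binding dissociation constant (nM); the binding of
#'   two dimers to DNA has equilibrium constant \eqn{K_{AR}^2 = k_{2R}/k_{1R}}.
#' @param p53_total Total p53 concentration (nM).
#' @param k1R Optional dimer-DNA association rate constant (nM^-2 h^-1);
#'   needed to map onto kinetic Hill parameters (default 0.01, a
#'   diffusion-limited order of magnitude).
#' @param k1d,k2d Optional dimerization rate constants; retained for
#'   bookkeeping only, since dimerization is assumed fast (quasi-steady
#'   state).
#' @return An object of class `dimer_system` with the inputs plus the
#'   derived `p53_dimer` and `p53_monomer` concentrations.
#' @examples
#' sys <- dimer_system(K_Ad = 8, K_AR = 10, p53_total = 40)
#' sustained_binding_dimer(sys)
#' @export
dimer_system <- function(K_Ad, K_AR, p53_total, k1R = 0.01,
                         k1d = NULL, k2d = NULL) {
  check_number(K_Ad, "K_Ad", lower = 0)
  check_number(K_AR, "K_AR", lower = 0, allow_lower = FALSE)
  check_number(p53_total, "p53_total", lower = 0)
  check_number(k1R, "k1R", lower = 0, allow_lower = FALSE)
  d <- dimer_concentration(K_Ad, p53_total)
  m <- p53_total - 2 * d
  # mass balance and equilibrium residual are construction invariants
  if (p53_total > 0) {
    stopifnot(abs((m + 2 * d) / p53_total - 1) <= 1e-10)
  }
  structure(
    list(K_Ad = K_Ad, K_AR = K_AR, p53_total = p53_total, k1R = k1R,
         k1d = k1d, k2d = k2d, p53_dimer = d, p53_monomer = m),
    class = "dimer_system"
  )
}

#' @export
print.dimer_system <- function(x, ...) {
  cat(sprintf(
    "<dimer_system> K_Ad = %g nM, K_AR = %g nM, total p53 = %g nM\n",
    x$K_Ad, x$K_AR, x$p53_total
  ))
  cat(sprintf("  dimer = %.4g nM, monomer = %.4g nM\n",
              x$p53_dimer, x$p53_monomer))
  invisible(x)
}

#' Sustained promoter binding of the dimerization system
#'
#' Asymptotic promoter-bound probability under sustained signaling,
#' \eqn{\bar P_{sus} = [\mathrm{p53}_2]^2/(K_{AR}^2 + [\mathrm{p53}_2]^2)},
#' with the dimer concentration from the equilibrium mass balance.  In the
#' strong-dimerization limit this reduces to a Hill curve in
#' \eqn{[\mathrm{p53}]_{total}} with exponent 2, in the weak limit with
#' exponent 4.
#'
#' @param sys A [dimer_system()] object.
#' @return A probability.
#' @export
sustained_binding_dimer <- function(sys) {
  stopifnot(inherits(sys, "dimer_system"))
  d <- sys$p53_dimer
  if (d == 0) return(0)
  1 / (1 + (sys$K_AR / d)^2)
}

#' Map the dimerization system onto plain Hill parameters
#'
#' In the strong-dimerization limit (\eqn{K_{Ad} \ll 4[\mathrm{p53}]_{total}},
#' read by default as \eqn{K_{Ad} \le 0.4\,[\mathrm{p53}]_{total}}) the
#' coupled system is exactly a Hill reaction with
#' `n = 2`, `K_A = K_AR`, signal = the dimer, and effective amplitude
#' \eqn{A = [\mathrm{p53}]_{total}/2}, so every other tool in the package
#' applies unchanged.  In the weak limit the correct mapping is `n = 4`,
#' \eqn{A = [\mathrm{p53}]_{total}}, \eqn{K_A^4 = K_{AR}^2 K_{Ad}^2} and
#' \eqn{k_1 = k_{1R}/K_{Ad}^2}.  With `limit = "auto"`, a system outside the
#' strong regime is refused with both limiting mappings reported rather than
#' silently approximated; pass `limit = "weak"` (or `"strong"`) to select a
#' mapping explicitly.
#'
#' @param sys A [dimer_system()] object.
#' @param limit `"auto"`, `"strong"` or `"weak"`.
#' @return A list of class `hill_map` with elements `params`
#'   ([hill_params()]), `amplitude` (nM) and `limit`.
#' @examples
#' sys <- dimer_system(K_Ad = 0.5, K_AR = 10, p53_total = 20)
#' effective_hill_map(sys)
#' @export
effective_hill_map <- function(sys, limit = c("auto", "strong", "weak")) {
  stopifnot(inherits(sys, "dimer_system"))
  limit <- match.arg(limit)
  strong_ok <- sys$K_Ad <= 0.4 * sys$p53_total
  strong_map <- list(
    params = hill_params(n = 2, k1 = sys$k1R, K_A = sys$K_AR),
    amplitude = sys$p53_total / 2, limit = "strong"
  )
  make_weak <- function() {
    if (sys$K_Ad == 0) {
      ph_abort("The weak-dimerization mapping is undefined at K_Ad = 0.")
    }
    list(
      params = hill_params(n = 4, k1 = sys$k1R / sys$K_Ad^2,
                           K_A = sqrt(sys$K_AR * sys$K_Ad)),
      amplitude = sys$p53_total, limit = "weak"
    )
  }
  if (limit == "auto") {
    if (!strong_ok) {
      wk <- make_weak()
      abort(
        paste0(
          "System is outside the strong-dimerization regime ",
          sprintf("(K_Ad = %g > 0.4 * p53_total = %g); ", sys$K_Ad,
                  0.4 * sys$p53_total),
          "refusing the automatic n = 2 mapping.\n",
          sprintf("  strong limit: n = 2, K_A = %g nM, A = %g nM\n",
                  strong_map$params$K_A, strong_map$amplitude),
          sprintf("  weak limit:   n = 4, K_A = %g nM, A = %g nM\n",
                  wk$params$K_A, wk$amplitude),
          "Select one explicitly with `limit = \"strong\"` or `\"weak\"`."
        ),
        class = "pulsehill_regime_error"
      )
    }
    limit <- "strong"
  }
  structure(if (limit == "strong") strong_map else make_weak(),
            class = "hill_map")
}

#' @export
print.hill_map <- function(x, ...) {
  cat(sprintf("<hill_map> %s-dimerization limit: n = %g, K_A = %g nM, A = %g nM\n",
              x$limit, x$params$n, x$params$K_A, x$amplitude))
  invisible(x)
}

#' Pulsing-regime scenario for a panel of promoters
#'
#' Maps each promoter (characterized by its binding constant `K_AR`) onto
#' effective Hill parameters via the strong-dimerization limit and
#' classifies its pulsing regime under a common p53 pulse train.  Promoters
#' differing only in affinity can land in different regimes — e.g. a
#' high-affinity cell-cycle-arrest promoter in the competitive regime while
#' low-affinity apoptosis promoters track the pulses in the slow regime —
#' which is the proposed reading of pulsed-versus-sustained expression
#' differences.
#'
#' @param promoters A data frame with columns `promoter` (name) and `K_AR`
#'   (nM), e.g. read from a two-column CSV.
#' @param signal A [square_wave()] whose `period` and `duty_cycle` describe
#'   the p53 pulse train; its amplitude is interpreted as the *total* p53
#'   pulse amplitude, so the effective dimer-signal amplitude is half of it.
#' @param K_Ad Dimerization constant (nM); must be in the
#'   strong-dimerization regime relative to the pulse amplitude.
#' @param k1R Dimer-DNA association rate constant (nM^-2 h^-1).
#' @inheritParams classify_regime
#' @return A tibble with one row per promoter: `promoter`, `K_AR`, `regime`,
#'   `x`, `graded`, `tau_sus`, `tau_pulsed`, `delay_factor`, `mean_binding`
#'   (period-averaged asymptotic binding) and `sustained_binding`.
#' @examples
#' panel <- data.frame(promoter = c("CDKN1A", "BAX"), K_AR = c(5, 32))
#' promoter_scenario(panel, square_wave(12, 6, 0.3), K_Ad = 1)
#' @export
promoter_scenario <- function(promoters, signal, K_Ad, k1R = 0.01,
                              threshold = 10, eps = 0.1) {
  stopifnot(is.data.frame(promoters), inherits(signal, "square_wave"))
  if (!all(c("promoter", "K_AR") %in% names(promoters))) {
    ph_abort("`promoters` needs columns `promoter` and `K_AR`.")
  }
  purrr::pmap_dfr(promoters[c("promoter", "K_AR")], function(promoter, K_AR) {
    sys <- dimer_system(K_Ad = K_Ad, K_AR = K_AR,
                        p53_total = signal$amplitude, k1R = k1R)
    map <- effective_hill_map(sys, limit = "strong")
    eff_sig <- square_wave(map$amplitude, signal$period, signal$duty_cycle)
    rep <- classify_regime(map$params, eff_sig, threshold = threshold,
                           eps = eps)
    tibble(
      promoter = promoter, K_AR = K_AR,
      regime = rep$regime, x = rep$x, graded = rep$graded,
      tau_sus = rep$tau_sus, tau_pulsed = rep$tau_pulsed,
      delay_factor = rep$delay_factor,
      mean_binding = mean_pulsed_binding(map$params, eff_sig),
      sustained_binding = sustained_binding(map$params, map$amplitude)
    )
  })
}
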