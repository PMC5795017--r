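---
title: "Pulsed Hill-type signaling: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsed Hill-type signaling: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsehill)
```

## The model and its assumptions

`pulsehill` describes a receptor R (typically a gene promoter) that is
activated when $n$ copies of a signal molecule S bind it:

$$n\mathrm{S} + \mathrm{R} \rightleftharpoons \mathrm{RS}_n,
\qquad K_d = K_A^n = k_2/k_1 .$$

Writing $P(t)$ for the probability that the receptor is bound, mass-action
kinetics give

$$\frac{dP}{dt} = (1-P)\,k_1[\mathrm{S}]^n - k_2 P .$$

Three assumptions are built in.  First, the signal pool is not depleted by
binding ($[\mathrm{S}] \gg [\mathrm{R}]$) — always true for a promoter
present in one or two copies per cell — so $[\mathrm{S}](t)$ is imposed
externally.  Second, the signal is an ideal square wave: amplitude $A$,
period $T$, duty cycle $\gamma$, with concentration $A$ on
$[(i-1)T,\,(i-1)T+\gamma T)$ and zero for the rest of each period.
Real p53 or calcium pulses have finite rise times and amplitude jitter;
none of that is modeled.  Third, the $n$ binding events are treated as one
cooperative step with a single pair of rate constants — the standard Hill
idealization.

Units follow the p53 application throughout: concentrations in nM, times in
hours, $k_1$ in nM$^{-n}$ h$^{-1}$ and $k_2$ in h$^{-1}$.  (Published
discussions of this system are not always consistent about the $k_1$ unit
prefix; the convention here is the one that makes $k_1 = 10^{-2}$
nM$^{-2}$ h$^{-1}$ with $K_A$ in the 1–64 nM range a sensible promoter
scenario.)

Because $[\mathrm{S}]$ is piecewise constant, the equation is linear within
every on/off segment and solves exactly: during a pulse $P$ relaxes toward
$\bar P_{sus} = A^n/(K_A^n + A^n)$ at rate $r = k_1A^n + k_2$, and between
pulses it decays at rate $k_2$.  Chaining segments yields the closed-form
piecewise solution evaluated by `analytic_binding()`, its $i\to\infty$
periodic orbit (`asymptotic_cycle()`), and the exact period-average
$\bar P_{pulsed}$ (`mean_pulsed_binding()`), which is obtained by
integrating the two exponential branches analytically rather than by
averaging a long simulation — deliberately, so that limit checks carry no
truncation error.

## Parameters that matter

- **$n$** (dimensionless, default free; 2 and 4 are the cases of practical
  interest): sets cooperativity.  The qualitative regime structure is
  insensitive to $n$ in the 2–4 range; quantitative shifts (titration,
  matched-mean ratios) scale as powers of $\gamma$ with exponent $n-1$ or
  $(n-1)/n$.
- **$k_1$** (nM$^{-n}$ h$^{-1}$): association rate, often
  diffusion-limited and therefore the better-known rate; the package
  parameterizes systems by $(n, k_1, K_A)$ or $(n, k_1, k_2)$
  interchangeably.
- **$K_A$** (nM): affinity; the 1–64 nM default grid of
  `scenario_grid()` covers the span reported for p53 target promoters.
- **$A$, $T$, $\gamma$**: the forcing.  $T = 6$ h and $\gamma = 0.3$ are
  the reference pulse train (p53-like); $\gamma = 1$ is sustained
  signaling, treated as a distinct status everywhere (classification,
  boundaries) rather than a degenerate regime.
- **`threshold`** (default 10) in `classify_regime()`: the operational
  reading of "much greater/less" in the pulsing-speed parameter
  $x = k_2(1-\gamma)T$.  $x \ge 10$ is slow (*d*), $x \le 0.1$ fast (*f*),
  otherwise competitive (*e*).  The dashed *boundary line* between
  competitive and fast behavior is drawn at the equality $x = 1$, the
  locus conventionally overlaid on the heatmaps, while the label uses the
  symmetric factor 10; both are exposed as arguments.
- **`eps`** (default 0.1): the reading of "$\ll$" in the graded-clocking
  conditions $k_2T \ll 1 - k_1A^n\gamma T$ and $k_1A^n\gamma T \ll 1$.

## Numerical choices

**Stable exponentials.**  Over the parameter ranges of interest $k_2T$
spans roughly $10^{-4}$ to $10^{3}$, so naive evaluation of the printed
solution overflows ($e^{k_2\Delta}$ terms) or cancels catastrophically.
Every exponential in the package is arranged with a non-positive exponent,
$1 - e^{-q}$ is always `-expm1(-q)`, and exponent differences such as
$r\Delta - iq$ are reduced algebraically (to $k_2(\Delta - T)$ and
relatives) before evaluation, never formed from large intermediates.  The
rising branch is rearranged so that the pulse-1 transient cancels exactly:
$P_1(\xi) = \bar P_{sus}(1 - e^{-r\xi})$ to the last bit, and the two
branches agree at the pulse edge and across period boundaries to better
than $10^{-13}\,\bar P_{sus}$ in randomized tests.

**Edge convention.**  On-intervals are half-open: the pulse-start instant
is on, the pulse-off instant is off.  Times are decomposed into pulse index
and phase with a snap tolerance of $10^{-9}T$ so that grid points
constructed as $kT + \Delta$ classify identically in the analytical
evaluator and in the integrator despite floating-point representation;
without this, an edge landing one ulp inside the on-state acquires a whole
spurious on-segment.

**Oracle and cross-check.**  The reference integrator
(`simulate_binding(method = "exact")`) is the exact per-segment exponential
update on a grid that contains every pulse edge, so it is immune to
stiffness by construction.  An adaptive `deSolve::lsoda` run (relative
tolerance $10^{-10}$, restarted at each edge) serves as an independent
cross-check; the analytic solution, the recursion and lsoda agree to
$10^{-8}$ or better across a thousand randomized parameter draws in the
test suite.

**Root finding.**  The half-saturation of a titration curve is found by
`uniroot` on the log-concentration axis to relative tolerance $10^{-6}$,
after verifying the grid brackets one-half; curves that never reach 0.5
report `NA` rather than an extrapolated value (see below).

**Degenerate inputs.**  $A = 0$ gives $P \equiv 0$ (or pure decay from a
nonzero start); $k_2 = 0$ makes the off-phase hold its level and
$\bar P_{sus} = 1$; $\gamma = 0$ is rejected at construction (the signal
would never appear), and $\gamma = 1$ is sustained signaling.

## Design choices where the design was open

**Delay boundary.**  The affinity below which pulsing significantly delays
binding is defined by $\tau_{pulsed} > \tau_{sus}$.  Solving the equality
with $k_2 = k_1K_A^n$ gives the quadratic
$(k_1A^n + k_2)(k_1A^n\gamma + k_2) = 2k_1A^n/T$, whose closed-form root is

$$K_A = \frac{A}{2^{1/n}}\left\{\left[(1-\gamma)^2 +
\frac{8}{k_1TA^n}\right]^{1/2} - (1+\gamma)\right\}^{1/n},$$

implemented in `delay_boundary()` and verified in the tests against direct
root-finding on $\tau_{pulsed} - \tau_{sus}$ to $10^{-6}$ relative.  When
the braced quantity is non-positive, no affinity delays binding and `NA`
is returned.  A transcribed variant of this boundary with an extra
$\gamma^{-1/n}$ in the prefactor circulates; it is inconsistent with the
rise-time expressions it derives from, and the package keeps the
self-consistent form.

**Half-saturation is absolute.**  The apparent dissociation constant is
the average concentration at which *half of all receptors* are bound.
Under slow pulsing with small duty cycle the pulsed curve saturates below
one-half (its plateau is
$\approx \gamma + (1-e^{-k_2(1-\gamma)T})/(k_2T)$, e.g. $0.4$ at
$\gamma = 0.3$, $k_2T = 10$), and then the half-saturation genuinely does
not exist; `titration_curve()` reports `NA` instead of silently switching
to a half-of-plateau definition.  The left shift of the titration curve is
still visible in its rising region, which the tests check directly.

**Dimerization limits converge at different rates.**  The p53 dimer
concentration solves the equilibrium-plus-mass-balance quadratic; the
package evaluates the root in conjugate form,
$[\mathrm{p53}_2] = 2\,\mathrm{tot}^2\big/\big(4\,\mathrm{tot} + K_{Ad} +
\sqrt{K_{Ad}^2 + 8K_{Ad}\,\mathrm{tot}}\big)$, which is exact algebraically
and cancellation-free across six orders of magnitude of
$K_{Ad}/\mathrm{tot}$ (the printed difference form loses up to five digits
at the weak end).  The strong-dimerization branch is approached only as
$\sqrt{K_{Ad}/(2\,\mathrm{tot})}$ — a 1% match on the occupancy needs
$K_{Ad} \sim 2\times10^{-5}\,\mathrm{tot}$ — whereas the weak branch
converges linearly, at $O(\mathrm{tot}/K_{Ad})$.  The
`effective_hill_map()` gate ($K_{Ad} \le 0.4\,\mathrm{tot}$ for the
automatic $n = 2$ mapping) is therefore a *regime* choice, not an accuracy
guarantee; outside it the mapping refuses and reports both limits, and the
weak $n = 4$ mapping ($A = \mathrm{tot}$, $K_A^4 = K_{AR}^2K_{Ad}^2$,
$k_1 = k_{1R}/K_{Ad}^2$) is available explicitly.  Dimerization itself is
assumed instantaneously equilibrated, and DNA-bound p53 is excluded from
the mass balance.

**Graded clocking linear window.**  Per-pulse levels follow
$P_i(T) = P_1(T)(1-e^{-iq})/(1-e^{-q})$ with
$q = k_1A^n\Delta + k_2T$, so proportionality $P_i \approx iP_1$ holds
while $iq \ll 1$.  The reported window is
$i \le 0.1\,\bar P_{pulsed}/P_1(T)$; at the $\varepsilon = 0.1$ condition
boundary this window holds a single pulse (the property is marginal there
by construction), and a multi-pulse staircase requires parameters well
inside the conditions — high affinity and short periods.

## Test design and problem sizes

Property tests run on randomized parameter draws with fixed seeds:
$n \in \{2,4\}$, $k_1$ log-uniform over $[10^{-4}, 10^{-1}]$, $K_A$
log-uniform over $[1, 64]$ nM, $A$ log-uniform over $[2, 100]$ nM,
$\gamma \in (0.05, 0.95)$, $T = 6$ h — the span of the reference scenario
grids.  Oracle-equivalence checks use 1000 draws over ten periods; branch
continuity 500 draws at $10^{-10}\bar P_{sus}$; limit recovery pins the
pulsing speed at $x = 100$ (slow) and $x = 0.01$ (fast) and measures the
deviation of the dimensionless suppression ratio, which is bounded by
$(1-\gamma)/x$ in the slow case — the limits are asymptotic, and at
$x = 100$ the ratio for small duty cycles is still visibly above $\gamma$
in *relative* terms while within 0.02 *absolutely*.  Cumulative-exposure
comparisons use runs tens of relaxation times long because the
accumulated-product ratio approaches its asymptote only as $O(\tau/t)$.

What passing these tests shows is internal and asymptotic consistency of
the implementation under ideal square-wave forcing.  It does not validate
the Hill idealization for any particular biological system, and none of the
fixtures are experimental data.

## Known limitations

- No receptor-pool depletion, no stochastic (low-copy) kinetics, no
  cell-to-cell variability.
- No downstream mRNA/protein dynamics; "product" here is bound receptor.
- Square waves only — no sinusoidal or measured waveforms.
- The p53 module covers the dimerization scheme and its two Hill limits
  only; other cooperative-binding mechanisms (e.g. pre-assembled
  tetramers) are out of scope beyond choosing $n$.
- Rate constants are taken as given; the package does not fit data.
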