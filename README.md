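# pulsehill

Many signaling molecules do not arrive as a steady level but as a train of
pulses: the tumor suppressor p53 after gamma irradiation, cytosolic calcium,
the yeast stress factor Msn2, circadian regulators.  When the downstream
step is *cooperative* — `n` copies of the signal molecule S must bind a
receptor R (a gene promoter, a channel) to activate it — the response to
pulsing is strongly non-linear, and whether a target is suppressed,
delayed, clocked, or driven up step-by-step depends on how the pulse
timing compares with the binding kinetics.

`pulsehill` implements this model end to end for R users: the exact
analytical solution of the forced binding equation, a numerical oracle, the
closed-form limiting laws, a regime classifier, and the dimerization-coupled
p53 promoter-binding application.

## The model

The signal is a square wave with amplitude `A` (nM), period `T` (h) and duty
cycle `γ` (on-fraction), forcing the bound-receptor probability `P(t)`
through Hill-type kinetics

```
dP/dt = (1 − P) k₁ [S]ⁿ − k₂ P,        K_d = K_Aⁿ = k₂/k₁ .
```

Because `[S]` is piecewise constant the equation solves exactly per pulse,
and the package evaluates that piecewise solution in a numerically stable
form, together with:

- `P̄_sus = Aⁿ/(K_Aⁿ + Aⁿ)` — the sustained-signaling asymptote;
- `P̄_pulsed` — the exact period-average of the limiting cycle, which tends
  to `γ·P̄_sus` for slow pulsing and `γAⁿ/(K_Aⁿ + γAⁿ)` for fast pulsing;
- the apparent dissociation constant under fast pulsing,
  `K′_A/K_A = γ^((n−1)/n)` — pulsing makes cooperative receptors *more*
  sensitive per unit of average signal;
- regime classification by `x = k₂(1−γ)T`: slow (*d*, binding tracks the
  pulses), competitive (*e*, binding outlasts each pulse), fast (*f*,
  binding sees only the average), and the graded-clocking sub-regime (*g*)
  in which binding steps up linearly with each pulse;
- rise times `τ_sus = 1/(k₁Aⁿ + k₂)` and
  `τ_pulsed = 1/(k₁(Aⁿγ + K_Aⁿ)) − (T/2)(1−γ)`, with the boundary affinity
  below which pulsing significantly delays activation;
- the p53 scheme: monomers dimerize (constant `K_Ad`), two dimers bind the
  promoter (constant `K_AR`), giving an effective Hill system with `n = 2`
  (strong dimerization) or `n = 4` (weak), mapped onto all of the above.

## Worked example

A low-affinity promoter (`K_A = 32` nM) under p53-like pulsing
(`A = 40` nM, `T = 6` h, `γ = 0.3`):

```r
library(pulsehill)

params <- hill_params(n = 2, k1 = 0.01, K_A = 32)
pulse  <- square_wave(amplitude = 40, period = 6, duty_cycle = 0.3)

sustained_binding(params, 40)      # 0.6097561
mean_pulsed_binding(params, pulse) # 0.1889783
classify_regime(params, pulse)
#> <regime_report>
#>   regime: slow_d  (x = k2(1-gamma)T = 43.01, threshold 10)
#>   graded clocking: FALSE
#>   tau_sus = 0.03811 h; tau_pulsed = -2.034 h (valid: FALSE)
#>   boundaries K_A (nM): fast 4.88, delay NA, graded NA
```

Sustained signaling would bind this promoter 61% of the time; pulsing at
duty cycle 0.3 cuts that to 19% — close to the slow-pulsing law
`γ·P̄_sus = 18.3%`, as expected at `x = 43`.  The titration curve against
the *average* signal concentration shows the apparent-affinity shift:

```r
glance(titration_curve(n = 2, duty_cycle = 0.3, k2T = 0.1, K_A = 32))
#>   n duty_cycle k2T K_A half_saturation     shift
#> 1 2        0.3 0.1  32        17.53428 0.5479464
```

so under fast pulsing half-occupancy needs only `0.55 × K_A` of average
signal (`√0.3 ≈ 0.548`).  Promoter panels map the p53 story directly:

```r
promoter_scenario(
  data.frame(promoter = c("CDKN1A", "BAX"), K_AR = c(5, 32)),
  square_wave(12, 6, 0.3), K_Ad = 1
)
#>   promoter K_AR        regime      x
#> 1   CDKN1A    5 competitive_e  1.050
#> 2      BAX   32        slow_d 43.008
```

— the high-affinity cell-cycle-arrest promoter stays bound between pulses
(regime *e*) while low-affinity apoptosis promoters simply track them
(regime *d*).

Trajectories, titration curves and `K_A`-by-time heatmaps are tibbles with
`autoplot()` methods; `simulate_binding()` provides the numerical
integrator; a thin CLI (`inst/cli/pulsehill`, subcommands `simulate`,
`regimes`, `titrate`, `grid`, `p53`) drives the same functions from the
shell and writes CSV/JSON.

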