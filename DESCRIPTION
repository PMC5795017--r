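Package: pulsehill
Title: Pulsed Hill-Type Signaling Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analytical and numerical tools for Hill-type binding kinetics
    driven by a square-wave (pulsed) signal, as arises for oscillatory
    transcription factors such as p53, calcium signaling and circadian
    clocks.  Provides the exact piecewise analytical solution of the
    forced binding equation, a per-segment exponential integrator used as
    a numerical oracle, closed-form steady-state and limiting-case
    quantities (suppression ratios, apparent dissociation-constant shift,
    titration curves, cumulative-exposure ratios), classification of
    slow/competitive/fast pulsing regimes including graded clocking, and
    a dimerization-coupled promoter-binding model for p53 that maps onto
    the plain Hill description.  Results are returned as tibbles with
    ggplot2 autoplot methods and broom-style tidiers; a small command
    line interface drives the same functions from the shell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
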