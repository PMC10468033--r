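# hhreduce

Steady-state reduction of order for Hodgkin–Huxley-type cell models,
demonstrated on a comprehensive uterine smooth muscle cell (uSMC) model.

## The problem

Conductance-based cell models describe each ion channel with gating
variables obeying first-order relaxation kinetics,

```
dx/dt = (x_inf(Vm) - x) / tau_x(Vm),      I_x = gbar_x * m^p * h^q * (Vm - E_x),
```

whose time constants can span six orders of magnitude within one model —
in the uSMC model used here, from ~0.1 ms (the BK K⁺ channel) to ~100 s
(the dominant voltage-gated K⁺ channel) — while the phenomena of interest
(action-potential bursts, Ca²⁺-driven force, organ-scale contraction) play
out over seconds and longer. Any gate with `tau_x` far below the time scale
of interest `T_i` can be replaced by its algebraic steady state
`x_inf(Vm)`, deleting one ODE per substitution. Combined with eliminating
low-impact channels by conductance (keeping one representative K⁺
channel), this takes the full 19-gating-ODE model down to 5 while
preserving its stimulated behaviour.

`hhreduce` is a toolkit for that workflow, aimed at modellers preparing
cell models for multi-scale (tissue/organ) simulation:

* **gating framework** — steady-state and time-constant curves, the exact
  closed-form relaxation at clamped voltage, voltage-grid profiling and
  range maxima (`gating_registry()`, `tau_profile()`, `max_tau()`,
  `tau_table()`);
* **channel submodels** — BK, T-type Ca²⁺, L-type Ca²⁺ and fast Na⁺ with
  complete closed-form kinetics, plus declared-only registry slots for the
  remaining source-model mechanisms (`chan_bk()`, `chan_cat()`,
  `chan_cal()`, `chan_na()`);
* **I–V scan comparator** — full-ODE versus steady-state gating at finite
  horizons, normalized to the all-ODE peak current (`iv_scan()`,
  `verify_candidate()`);
* **whole-cell simulator** — stiff BDF integration (tolerances 1e-7,
  max step 0.1 ms) of configurable variants with per-gate ODE/SS mode
  switching, rest-state root solving and stimulus protocols
  (`simulate_cell()`, `resting_state()`, `ssp()`);
* **reduction toolkit** — conductance ranking, the `tau_x <= 0.01 * T_i`
  candidate screen, reduction plans and range-normalized trace comparison
  (`rank_conductances()`, `identify_ss_candidates()`, `apply_reduction()`,
  `compare_traces()`).

Everything returns tibbles that pipe into dplyr/ggplot2 (`autoplot()`,
`tidy()`, `glance()` methods included). A thin command-line front end
lives in `inst/cli/hhreduce.R` (subcommands `profile-tau`, `iv-scan`,
`simulate`, `compare`, `identify`, `reduce`, `fixtures`).

## Worked example

Profile the relaxation time scales, screen for substitution candidates at
a 1 s time scale of interest, verify one channel by clamped scans, and
apply the published reduction plan:

```r
library(hhreduce)

tau_table()
#> # A tibble: 9 × 4
#>   variable role         `max_tau_ms_-100_200` `max_tau_ms_-80_20`
#> 1 x_alpha  activation                    2.41               0.298
#> 2 x_beta   activation                   13.8                2.76
#> 3 b        activation                    4.35               4.35
#> 4 g        inactivation                149.               138.
#> 5 d        activation                    7.99               7.99
#> 6 f1       inactivation                 12                 12
#> 7 f2       inactivation                 91.0               91.0
#> 8 m        activation                    7.24               7.15
#> 9 h        inactivation                903.               903.
```

Each row is one gating variable; the columns give its maximum relaxation
time constant (ms) on an integer 1-mV grid over a beyond-physiological
and a physiological voltage window. Five variables stay below the 10 ms
rule-of-thumb threshold for a 1 s time scale of interest on the ±50 mV
span, and the screen flags exactly those:

```r
identify_ss_candidates(preset_demo(), T_interest = 1, V_span = c(-50, 50))
#>   variable channel role         max_tau_ms threshold_ms flagged
#> 1 d        CaL     activation        7.99            10 TRUE
#> 2 f1       CaL     inactivation     12               10 FALSE
#> 3 f2       CaL     inactivation     91.0             10 FALSE
#> 4 b        CaT     activation        3.28            10 TRUE
#> 5 g        CaT     inactivation     41.1             10 FALSE
#> 6 m        Na      activation        5.63            10 TRUE
#> 7 h        Na      inactivation    903.              10 FALSE
#> 8 x_alpha  BK      activation        0.450           10 TRUE
#> 9 x_beta   BK      activation        4.06            10 TRUE
```

The screen is a screen, not a verdict — clamped-voltage scans quantify the
actual substitution error at the horizons of interest (the T-type
inactivation gate fails the rule yet improves sharply with horizon; the
residual concentrates below the resting potential, where little current
flows during activity):

```r
verify_candidate(chan_cat(), c("b", "g"), horizons = c(10, 100))
#>   channel variables horizon_ms max_abs_dI
#> 1 CaT     b+g               10      0.437
#> 2 CaT     b+g              100      0.343
```

Reduction plans are explicit and composable; the published plan removes
three K⁺ channels (K1 becomes the representative K⁺ current), switches
eight gates to steady state and retunes three conductances and the Ca²⁺
buffering fraction:

```r
ftm <- preset_ftm()
rtm <- apply_reduction(ftm, list(
  disable = c("K2", "Ka", "h"),
  ss = c("x_alpha", "x_beta", "b", "g", "d", "f1", "m", "h"),
  exchangers_off = "NaK",
  overrides = list(gbar = c(CaL = 0.6, Na = 0.0895, K1 = 0.7), beta = 0.0169)))
c(count_gating_odes(ftm), count_gating_odes(rtm))
#> [1] 19  5
```

The channels beyond the four with complete in-package kinetics are
declared-only (names, conductances and gate identities, no rate
expressions), so the 19→5 bookkeeping, ranking and planning all work, but
simulating the full/reduced source-model variants requires a validated
transcription of the remaining expressions, which this package does not
bundle; `preset_demo()` is a fully simulatable variant built from the
in-package channels plus labelled synthetic leaks. See the methods
vignette (`vignettes/model-reduction.Rmd`) for the model equations,
parameter defaults and design decisions.

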