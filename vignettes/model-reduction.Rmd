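---
title: "Steady-state reduction of order for a uterine smooth muscle cell model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state reduction of order for a uterine smooth muscle cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Conductance-based (Hodgkin–Huxley-type) cell models track each ion channel
with activation/inactivation gating variables $x$ obeying first-order
kinetics,

$$\frac{dx}{dt} = \frac{x_\infty(V_m) - x}{\tau_x(V_m)},$$

and compute each membrane current as
$I_x = \bar g_x\, m_x^{p} h_x^{q} (V_m - E_x)$ with driving force relative
to the (typically Nernstian) reversal potential $E_x$. In the uterine
smooth muscle cell (uSMC) model this package works with, nineteen such
gating ODEs span relaxation time scales from fractions of a millisecond
(the Ca^2+^-activated BK K^+^ channel) to hundreds of seconds (the
dominant voltage-gated K^+^ channel), while the physiology of interest —
bursts of action potentials, Ca^2+^-driven force generation, organ-scale
contraction — unfolds over seconds to minutes. Whenever
$\tau_x \ll T_i$, the time scale of interest, the gating ODE can be
replaced by its algebraic steady state $x_\infty(V_m)$ with negligible
error, deleting one state dimension per substitution. `hhreduce`
implements that reduction workflow end to end:

1. **profile** relaxation time constants over voltage
   (`tau_profile()`, `max_tau()`, `tau_table()`);
2. **screen** for substitution candidates with the rule of thumb
   $\max_{V \in V_{span}} \tau_x \le 0.01\, T_i$
   (`identify_ss_candidates()`);
3. **verify** candidates against clamped-voltage I–V scans comparing
   full-ODE with steady-state gating at finite horizons
   (`iv_scan()`, `verify_candidate()`);
4. **apply** a reduction plan — disable low-impact channels, switch gates
   to SS mode, adjust conductances (`apply_reduction()`,
   `rank_conductances()`);
5. **quantify** fidelity of the reduced variant on simulated traces
   (`simulate_cell()`, `compare_traces()`).

## The whole-cell model

State variables are membrane potential $V_m$ (mV), free cytosolic
$[\mathrm{Ca}^{2+}]_i$ (nM), the contractile activation fraction
$\omega$, and the ODE-mode gating variables. Units are fixed
package-wide: mV, ms, nM, pA/pF, nS/pF.

Membrane potential integrates the per-capacitance current balance

$$\frac{dV_m}{dt} = -\Big[\textstyle\sum_x I_x + I_{app}\Big],$$

so currents in pA/pF are numerically mV/ms and a *negative* applied
current depolarises; this orientation is fixed by the stimulated traces,
in which the $-0.5$ pA/pF standard stimulus drives action potentials
above 0 mV from a rest near $-58$ mV.

Free Ca^2+^ balances buffered influx against extrusion,

$$\frac{d[\mathrm{Ca}]_i}{dt} = \beta\,(J_{CaL} + J_{CaT} + J_{NSCC})
  - J_{NCX} - J_{PMCA},$$

with $\beta$ the fraction of Ca^2+^ influx that stays free (0.015 in the
full model; a fitting degree of freedom in reduced variants). The
conversion from a membrane current in pA/pF to a concentration flux in
nM/ms is geometry-dependent and not a printed model constant; it lives in
`ModelConfig$flux_conversion` with default 26 nM·ms^-1^ per pA/pF,
estimated from a typical uSMC (capacitance ≈ 20 pF, accessible volume
≈ 4 pL, divalent charge): $I \cdot C_m / (2 F V_{cell})$.

Force activation follows first-order kinetics toward a Hill function of
Ca^2+^ with half-activation $K_{mF} = 160$ nM and coefficient
$n_F = 3.6$; its time constant runs from 4 s (low Ca^2+^) down to
0.94 s (saturation), which is why force is never a steady-state
substitution candidate (`force_model()`).

## Channel submodels

Four channels ship with complete closed-form gating (steady states and
time constants): the BK K^+^ pair $x_\alpha, x_\beta$ (mixing weights
0.65/0.35), T-type Ca^2+^ $b^2 g$, L-type Ca^2+^
$d^2 f_{Ca} (0.8 f_1 + 0.2 f_2)$ (with $\tau_{f1}$ fixed at 12 ms) and
fast Na^+^ $m^3 h$. The remaining source-model mechanisms (K1, K2, Ka,
the hyperpolarisation-activated current, ANO1, NSCC, the NCX/PMCA/Na-K
transport systems) are *declared-only* in this package: their identities,
conductances and gating-variable names are registered, so ODE counting,
conductance ranking and reduction planning work on the full 19-ODE
variant, but their rate expressions are not bundled and any attempt to
evaluate their currents raises an informative error. A validated
transcription of those expressions from the archived implementation of
the source model would drop into the same `channel()` registry; shipping
an unvalidated guess would be worse than shipping none.

Two pieces of the four closed-form channels are likewise unavailable and are replaced by clearly-labelled surrogates:

* the L-type Ca^2+^-desensitisation factor $f_{Ca}$ defaults to 1;
* the BK steady states depend on Ca^2+^ through gating-charge and
  half-voltage functions that are not printed. The package substitutes
  Boltzmann curves whose midpoints shift $-60$ mV per decade of Ca^2+^,
  with the $x_\beta$ component (the slower of the pair, associated with
  regulatory-subunit channels) left-shifted 130 mV relative to
  $x_\alpha$ — regulatory-subunit association left-shifts BK activation
  physiologically. The shift magnitude and slopes (18 and 24 mV) were
  calibrated once against the published behaviour of the BK clamp scans
  (steady-state substitution indistinguishable from the full ODE over the
  physiological range at a 10 ms horizon, with only a small residual
  toward strongly depolarised potentials), since that scan behaviour is
  the only quantitative constraint the published material puts on these
  curves. BK time constants are the published expressions.

Reversal potentials are fixed package defaults — $E_K = -84$ mV (the
printed background-current equilibrium), $E_{Ca} = +45$ mV,
$E_{Na} = +55$ mV — with a Nernst mode (`reversal_nernst()`) available,
used e.g. to recompute $E_K$ under the elevated-extracellular-K^+^ pulse
protocol.

## I–V scans and the holding convention

`iv_scan()` clamps each grid potential, initialises every gate at its
steady state for a holding potential, advances ODE-mode gates with the
exact closed-form relaxation (exact because the clamp is constant within
a scan point, and doubling as the oracle for the stiff integrator),
evaluates SS-mode gates algebraically, and normalises currents by the
peak magnitude of the all-ODE curve.

The holding potential defaults to $-55$ mV, the model's resting
potential. This choice matters only for slow inactivation gates, but
there it is decisive: initialised at rest, the T-type scan deviations
concentrate below the resting potential (where $\tau_g$ exceeds 100 ms)
and the at-or-above-rest deviation falls roughly an order of magnitude
when the horizon grows from 10 ms to 100 ms — the structure the
reduction methodology relies on. A deeply hyperpolarised holding level
(e.g. $-80$ mV) instead loads the slow gate far from every steady state
on the interesting part of the grid and makes the steady-state scan
diverge from the full-ODE scan almost everywhere, which would say
nothing about substitution quality during activity from rest. Activation
gates are insensitive to the choice at these horizons.

## Numerical choices

* **Integrator**: backward-differentiation (BDF) stiff stepping via
  deSolve, absolute and relative tolerances $10^{-7}$, maximum step
  0.1 ms; traces are resampled on a uniform 1 ms grid so variants are
  comparable regardless of adaptive stepping. Halving tolerances moves a
  stimulated demo trace by well under 0.1 mV.
* **Rest states** are found by a nested one-dimensional root solve
  (inner: Ca^2+^ flux balance at fixed $V_m$, by bisection on a bracket
  spanning 10^-3^–10^6^ nM; outer: zero total membrane current, by
  scanning 31 probes over $[-95, -20]$ mV for a sign change and
  polishing with `uniroot` at $10^{-12}$ tolerance). Configurations whose
  residual is identically zero (all channels disabled) return the
  caller's guess. The returned state satisfies
  $\lVert \mathrm{RHS} \rVert < 10^{-8}$.
* **Gating safety**: the solver clamps gating values into $[0,1]$ and
  Ca^2+^ to a $10^{-6}$ nM floor before evaluating the right-hand side;
  trajectories at default tolerances never engage the clamp beyond
  $10^{-6}$.
* **Tabulated maxima** use integer 1-mV grids. This is deliberate: the
  sharp Na^+^ inactivation peak sits at $-47.5$ mV, off the integer
  grid, and the published maximum (903.46 ms ≈ the value at $-47$ mV) is
  an integer-grid maximum, not the analytic peak (≈ 1003.75 ms).
* **Relative trace difference** is pointwise
  $|x_{red}(t) - x_{ref}(t)| / (\max_t x_{ref} - \min_t x_{ref})$ —
  range normalisation keeps the metric well defined for signals crossing
  zero ($V_m$); the metric name is recorded in every comparison report.
* **Tie-breaks**: equal conductances rank lexicographically by channel
  id, for determinism.

## The demo variant

`preset_demo()` is invented plumbing, clearly labelled as such: the four
fully-specified channels plus a linear K^+^ leak (0.05 nS/pF,
$E = -84$ mV), a linear nonselective leak (0.0123 nS/pF, $E = 0$ mV) and
a linear Ca^2+^ clearance (rate 2×10^-4^ ms^-1^, a PMCA-like surrogate)
closing the Ca^2+^ balance. Its purpose is to make assembly,
integration, rest-state solving, mode switching and comparison testable
end to end with zero transcribed content. It rests near $-75$ mV with
Ca^2+^ near 100 nM and is deliberately leak-dominated and
non-oscillatory; it does *not* emulate uSMC bursting, Ca^2+^ stair-step
dynamics or the K^+^-channel repertoire, so tests passing on it
demonstrate the machinery, not full-model electrophysiology. Everything
quantitative about the published reduction that is testable without the
transcribed registry — the time-constant table, the candidate screen,
the ODE-count arithmetic, the scan-based substitution errors — is tested
directly on the closed-form expressions instead.

Problem sizes in the shipped tests and acceptance script were chosen to
make every check sharp but cheap: 301-point integer voltage grids for
tabulated maxima, 161-point scans for I–V deviations, 5-mV grids with
three horizons for the integrator-versus-closed-form oracle, and demo
simulations of 1–10 s.

## Known limitations

* The full and reduced source-model variants (`preset_ftm()`,
  `preset_rtm()` and relatives) are bookkeeping-complete but not
  simulatable without a validated transcription of the source model's
  remaining rate expressions; the fidelity claims that depend on them
  (sub-1% $\Delta V_m$ under BK substitution in the full model; the
  reduced model's action-potential burst and stair-step Ca^2+^ rise
  under the standard stimulus) are encoded as tests that fail
  informatively rather than silently passing on surrogates.
* The BK surrogate reproduces the published scan behaviour but is not
  the source model's Ca^2+^ dependence; conclusions about BK gating away
  from the calibrated regime (very high Ca^2+^, strong depolarisation)
  should not be drawn from it.
* Spatial (tissue-scale) coupling, dynamic Na^+^/K^+^/Cl^-^
  concentrations, sarcoplasmic-reticulum Ca^2+^ stores, stochastic
  gating and formal sensitivity/bifurcation analysis are out of scope.
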