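---
title: "Methods: dose-response alignment in coupled GTPase switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response alignment in coupled GTPase switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doraswitch)
```

## The model

`doraswitch` implements a six-variable signaling cascade: a receptor
(`R*`), a monomeric GTPase switch (`mGEF`, `mG*`, `mGAP`) and a
heterotrimeric GTPase switch (`tGEF`, `tG*`), coupled by a negative
feedback from the second switch back onto mGAP production. The dynamic
variables are fractional activations (`R*`, `mG*`, `tG*`, each in
\[0, 1\]) and concentrations (`mGEF`, `tGEF`, `mGAP`). With `f` the
reaction kinetics and `F` the feedback gate, the system is

\[
\begin{aligned}
\dot R^* &= k_{on}^{R} f(S)(1-R^*) - k_{off}^{R} R^* \\
\dot{mGEF} &= k_{on}^{mGEF} f(R^*) - k_{off}^{mGEF}\, mGEF \\
\dot{mG}^* &= k_{on}^{mG} f(mGEF)(1-mG^*) - k_{off}^{mG} f(mGAP)\, mG^* \\
\dot{tGEF} &= k_{on}^{tGEF} f(mG^*) - k_{off}^{tGEF}\, tGEF \\
\dot{tG}^* &= k_{on}^{tG} f(tGEF)(1-tG^*) - k_{off}^{tG} f(tGAP)\, tG^* \\
\dot{mGAP} &= k_{on}^{mGAP} + k_{feedback} F(tGEF, tG^*)
             - k_{off}^{mGAP}\, mGAP
\end{aligned}
\]

`tGAP` is a constant parameter, not a state variable. Two kinetics are
supported — mass action, `f(x) = x`, and Hill,
`f(x) = x^n / (K^n + x^n)` — and three feedback gates: none (`F = 0`),
AND (`F = f(tGEF) f(tG*)`) and OR (`F = f(tGEF) + f(tG*)`), giving six
model variants (`model_spec()`).

## Dose-response alignment and the distance metric

A downstream species shows dose-response alignment (DoRA) when its
normalized steady-state dose-response curve tracks the normalized
receptor occupancy. Curves are normalized by their own
infinite-stimulus activation levels (`activation_levels()`), so
`u = R^*_{ss}/R^*_{ss,max}` and `v = Y_{ss}/Y_{ss,max}` both approach 1.
The distance metric is

\[
\int_0^\infty |v - u| \frac{du}{dS}\, dS \;=\; \int_0^1 |v - u|\, du,
\]

the area between the curve `v(u)` and the diagonal; zero means perfect
alignment. `dora_metric()` evaluates the area form by the trapezoidal
rule on the `u`-ordered samples, appending the exact analytic endpoint
`(1, 1)` because the finite dose grid truncates the `S -> Inf` tail.
`metric_area_equivalence()` cross-checks the two printed forms: the
dose-weighted form uses the closed-form receptor derivative
(`receptor_steady_deriv()`) and a 4001-point dose grid by default, at
which the two quadratures agree to order `1e-6` on sampled models (the
discrepancy is pure quadrature error and converges away under
refinement).

Analytic anchors used in the tests: the saturated curve `v = 1` has
metric `1/2`, and the Michaelian curve `v = (1+a)u/(u+a)` has metric
`(1+a)(1 - a log((1+a)/a)) - 1/2` (for `a = 1`, `3/2 - 2 log 2 ≈
0.1137`), verified independently by adaptive quadrature.

## Steady-state computation

Three routes are implemented and cross-checked against each other:

* **Scalar fixed point** (`steady_state_fixed_point()`, the default in
  `dose_response()`). The receptor solves in closed form; every other
  component is an explicit function of `y = mG^*_{ss}`. The residual
  `y - g(y)` is monotone, so the root on \[0, 1\] is unique and found by
  `stats::uniroot()` to a `1e-12` tolerance. A missing sign change is
  surfaced as an error (possible multistability) rather than resolved.
* **Stiff integration** (`steady_state_ode()`): `deSolve::ode()`
  (`lsoda`, `atol = 1e-12`, `rtol = 1e-10`) from the all-zero initial
  state, in geometric time chunks up to `t = 1e8`, with early exit once
  `max |dx/dt| < tol (1 + |x|)` componentwise. Non-convergence is an
  error carrying the residual, never silently clipped.
* **Closed forms** for the no-feedback variants
  (`analytic_mass_action_steady()`, `analytic_hill_steady()`), via the
  composite constants of `derived_constants()`. Note that the composite
  `a_H` multiplying the Hill closed form is the *reciprocal* rate ratio
  `(k_off^{mG}/k_on^{mG}) f_{act}(mGAP_{ss})` — the form required for
  `mG^* = F_1/(F_1 + a_H)` to solve the steady-state balance — and
  likewise for `b_H`; this was validated against the ODE route on
  random rate constants.

The acceptance suite requires the three routes to agree within `1e-6`
per component across random parameter sets for all six variants.

## Parameters, defaults and units

All rate constants are first-order (per unit time) and default to 1,
with `k_feedback = 0` and `tGAP = 1` (`kinetic_parameters()`). Under
mass action this puts the composite `a_M` at 1 and the mGTPase
activation level at exactly 0.5, the middle of its range. Hill kinetics
default to `K = 0.5`, `n = 1.5` shared by all reactions: the arguments
of `f` are fractional activations or order-one concentrations, so
`K = 0.5` is a half-maximal constant in the middle of the operating
range, and `n = 1.5` is the cascade-comparison baseline (with `n = 3`
as the steeper alternative).

Doses span `[1e-5, 1e3]` on a 60-point logarithmic grid by default
(`default_dose_grid()`); the range is the study's stated stimulus
range, the density a convergence-checked choice.

## Parameter-space generation

`sample_parameter_space()` draws log-uniform samples, the natural scale
for rate constants spanning decades. Default ranges are `[1e-2, 1e1]`
per rate constant, `[0.01, 1]` for the constitutive mGAP production
rate and `[0, 10^2.6]` for the feedback strength. Default spaces are
`{k_on_mG, k_on_tG, k_on_mGAP}` (mass action) plus `k_on_R` (Hill,
where the receptor limit is tunable); feedback-trend sweeps sample
`{k_on_mG, k_on_tG}` (mass action) or `{k_on_R, k_on_mG, k_on_tG}`
(Hill) around a base template with `k_on_mGAP = 0.01`. That base
follows the analysis assumption that constitutive mGAP production is
small relative to the feedback term; with the generic `k_on_mGAP = 1`
the AND gate is doubly saturated at low activation and feedback-strength
trends flatten out. `preset_for_regime()` rejection-samples until the
computed activation level falls in `[0.8, 1]`, `[0.35, 0.65]` or
`[0, 0.2]` — operational thresholds for the qualitative labels "high",
"intermediate" and "low". All generators are deterministic under their
seed and restore the caller's RNG state.

Realism limits: samples are independent log-uniform draws, not
parameters fitted to any biological system; absolute time and
concentration scales are arbitrary. Conclusions should be read as
statements about the sampled spaces, not about measured kinetics.

## Sweeps, trends and comparisons

`sweep_single_parameter()` re-evaluates the metrics along one swept
constant; `classify_trend()` labels the sign pattern of successive
differences after discarding relative changes below 1% (the tolerance
that separates solver noise from real non-monotonicity at the default
grid sizes), recognizing at most one sign change and flagging anything
else as ambiguous. Feedback sweeps use `{0} ∪` eight log-spaced points
up to `10^2.6` (`feedback_grid()`); the zero point is handled by the
degenerate no-feedback path because the closed-form derivative (below)
is singular there.

For the AND/OR comparison, `match_or_feedback_strength()` enforces
equal mGTPase activation levels: at the infinite-stimulus fixed point
both gates must produce the same mGAP, giving the closed form
`k_{OR} = k_{AND} f(tGEF_{max}) f(tG^*_{max}) /
(f(tGEF_{max}) + f(tG^*_{max}))`, which is exact for both kinetics and
is verified (and polished) by bracketed root-finding on the activation
mismatch. `compare_logic_gates()` summarizes the paired metrics by the
mean perpendicular distance to the diagonal; `compare_cascade()` counts
pairs where the tGTPase metric beats the mGTPase metric.

The closed-form sensitivity of the normalized mGTPase curve to the
feedback strength (`feedback_derivative_mass_action()`, mass action
only) evaluates `(1/y)\,\partial y/\partial k_{feedback} =
-(1/k_{feedback})\big[(y/h)\,\partial h/\partial y +
((c+h)/h)/(1-y)\big]^{-1}` at `y = mG^*_{ss}(S)` and at the activation
level, and `metric_derivative_wrt_feedback()` differentiates the metric
under the integral (valid because the normalized mGTPase curve never
drops below the receptor curve under mass action). Both are
cross-checked against central finite differences with relative step
`1e-4`; the Hill-side metric derivative is finite-difference only, as
no closed form is available.

## Numerical edge cases and limitations

* Deeply composed Hill functions underflow: at `n = 3` a weakly driven
  cascade can give a tGTPase activation level that is exactly 0 in
  double precision. Normalization then fails loudly; sweep pipelines
  record such sets as failed rows instead of aborting.
* The root polish of the matched OR strength is limited by the
  steady-state solver's noise floor when the activation level barely
  depends on `k_{feedback}` (tiny matched strengths under Hill
  kinetics); the closed form remains exact.
* Steady states are assumed unique (the fixed-point residual is
  monotone for this vector field); no bifurcation or stability analysis
  is attempted, and multistable configurations would surface as
  explicit errors.
* Figure-level claims are reproduced qualitatively on seeded sampled
  spaces; the original per-figure parameter values are not available,
  so no numerical point-cloud is reproduced exactly.
* Transient dynamics, stochastic simulation, spatial effects and
  receptor-number variation are out of scope.

## A worked example

```{r example, eval = FALSE}
library(doraswitch)

spec <- model_spec("mass_action", "none")
params <- kinetic_parameters(k_on_mGAP = 0.1)
curve <- dose_response(params, spec)
norm <- normalize_curves(curve)
dora_metric(norm, "mG")
dora_metric(norm, "tG")
```

Experiments are reproducible end to end through the config interface
(`validate_config()`, `run_experiment()`), which copies the parsed
config, a log and an MD5 manifest next to every result table.
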