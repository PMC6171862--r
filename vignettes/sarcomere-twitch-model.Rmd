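---
title: "A spatially resolved mechano-chemical model of the cardiac isometric twitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatially resolved mechano-chemical model of the cardiac isometric twitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcotwitch)
```

## The model

Cardiac muscle relaxes more slowly when it has developed more tension.
`sarcotwitch` simulates the isometric twitch of a cardiac sarcomere under
the hypothesis that this is a local, mechanical effect: tension in the
thin filament tightens the binding of Ca²⁺ to troponin, so the parts of
the filament under the most load are the last to deactivate.

The working domain is the *single-overlap region* of the thin filament —
the only span where cross-bridges can form — parameterised by arc
position $x$ from the mid-line-proximal edge ($x = 0$) to the
z-disk-proximal edge ($x = L_{so}$). Three coupled relations govern the
field of force-generating cross-bridges $A(x,t)$:

1. **Troponin activation (steady-state, tension-shifted logistic).** The
   fraction of active troponins is
   $$P(x,t) = \frac{1}{1 + e^{\,n\left(-C_s S(x,t) - \ln \frac{[Ca^{2+}](t)}{K_{TnCa0}}\right)}},$$
   where $n$ is the chemical Hill coefficient at zero load, $C_s$ (kPa⁻¹)
   the tension sensitivity, and $K_{TnCa0}$ the zero-tension calcium
   equilibrium constant. Treating calcium binding as instantaneous is
   justified because the cross-bridge cycle, not calcium exchange, is
   rate-limiting.

2. **Length-dependent affinity.** $K_{TnCa0} = -a\,L_{sarc} + b$: longer
   sarcomeres bind calcium more avidly, the model's expression of
   length-dependent activation.

3. **Two-state cross-bridge cycle and tension accumulation.**
   $$\frac{\partial A}{\partial t} = (1 - A)\,P\,f_{DA} - A\,f_{AD},
   \qquad
   \frac{\partial S}{\partial x} = C_f\,A, \quad S(0,t) = 0.$$
   Force density is proportional to local cross-bridge occupancy, so
   tension accumulates from the loose end toward the z-disk; the total
   sarcomere tension is $S(L_{so}, t)$. The feedback loop closes through
   $P$: accumulated tension deepens calcium binding downstream.

Because $S(0,t)=0$ always, there is a permanently loose end near the
mid-line. As the calcium transient decays, relaxation begins there and
sweeps outward; near the z-disk, where $S$ is maximal, deactivation is
energetically penalised and relaxation is delayed. That spatial gradient
of relaxation onset is the model's central, testable property.

## Inputs

The twitch is driven by a prescribed two-exponential calcium transient
$$Ca(t) = Ca_{dias} + \frac{Ca_{peak} - Ca_{dias}}{\beta}
\left[e^{-(t-t_0)/\tau_{decay}} - e^{-(t-t_0)/\tau_{rise}}\right],$$
with $\beta$ the closed-form maximum of the bracketed term so the peak
equals `ca_peak` exactly. There is no calcium-handling model and no force
feedback on calcium: the transient is an input, uniform in space.

Single-overlap length follows the standard filament geometry
$L_{so} = \min(l_{thick}/2,\ L_{sarc}/2) - \max(L_{sarc}/2 - (L_{sarc} -
l_{thin}),\ l_{bare}/2)$, giving 650 nm at $L_{sarc} = 2.05$ µm with the
default constants ($l_{thin} = 1.2$, $l_{thick} = 1.65$, $l_{bare} =
0.1$ µm).

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| $a$ | 1.39 | µM µm⁻¹ | slope of $K_{TnCa0}$ vs length |
| $b$ | 7.76 | µM | intercept of $K_{TnCa0}$ |
| $n$ | 3 | — | zero-load Hill coefficient |
| $C_s$ | 0.127 | kPa⁻¹ | tension sensitivity of troponin |
| $C_f$ | 0.283 | kPa nm⁻¹ | tension per unit length at full occupancy |
| $f_{DA}$ | 40 | s⁻¹ | cross-bridge attachment rate |
| $f_{AD}$ | 12 | s⁻¹ | cross-bridge detachment rate |

Calcium block: diastolic 0.09 µM, peak 1.45 µM, $\tau_{rise}$ 0.02 s,
$\tau_{decay}$ 0.11 s, onset $t_0$ 0.05 s. The shape parameters are the
published values of the prescribed-transient formulation this model
adopts; the onset default represents the electromechanical delay between
stimulus and calcium release and only shifts the absolute time base —
durations, tensions and activation levels are independent of it. All of
these are exposed in the run configuration.

Two degenerate parameter settings are deliberately permitted: $a = 0$
(no length dependence) and $C_s = 0$ (no tension feedback). The second
collapses the field to a single spatially uniform cross-bridge ODE and
anchors one of the test suite's strongest oracles.

## Numerics

The field is discretised by the method of lines: `n_x` samples
(default 101) on a uniform closed grid over $[0, L_{so}]$. The tension
integral uses the trapezoidal rule by default; a left-endpoint cumulative
sum is available (`quadrature = "riemann"`) as the strict first-order
analogue, and the two agree as the grid refines. Time integration uses
`deSolve::lsoda` (rtol 1e-6, atol 1e-9 by default): the contract is
accuracy, verified by convergence tests (peak tension stable to < 0.5%,
$t_{R50}$ to < 2 ms under grid doubling and tolerance tightening), not a
particular scheme. The initial condition is the diastolic equilibrium
profile, computed by fixed-point iteration at `ca_diastolic`, so traces
start at rest without a startup transient. Output is sampled at 1 ms,
comfortably resolving peak and relaxation times; `t_end` defaults to
1.0 s and the result carries a flag if 50% relaxation was not reached.

Twitch metrics: peak tension is the trace maximum; $t_{R50}$ is the time
from the peak to the first crossing of 50% of the peak, located by
linear interpolation between samples. Resting tension is essentially
zero, so 50%-of-peak and 50%-of-amplitude coincide.

## Protocols

* **Length sweep** — 7 lengths, 1.90–2.20 µm in 0.05 µm steps, identical
  transient (peak 1.45 µM). Peak tension rises essentially linearly with
  length (the sweep's least-squares $R^2$ exceeds 0.98) and $t_{R50}$
  grows with it.
* **Calcium-amplitude sweep** — fixed $L_{sarc} = 2.2$ µm; the
  above-diastolic amplitude is scaled stepwise (default 60–100% in five
  10% steps, a design choice: the step count is not prescribed), with
  rise and decay constants unchanged. This separates the effect of peak
  tension from length-dependent affinity.

`scale_amplitude` preserves the diastolic level and scales the amplitude
above it. With a 0.09 µM diastolic level, the 60% fraction gives a peak
of 0.906 µM; where a condition is defined by a target *peak
concentration* (e.g. 0.87 µM), the fraction is chosen to hit that peak
exactly — the package's reference checks do this.

One behaviour worth knowing: across the amplitude sweep, $t_{R50}$ is
biphasic. Below roughly 80% amplitude the twitch is weak, relaxation is
calcium-decay-limited, and $t_{R50}$ *shrinks* slightly with amplitude
as the tension peak sharpens; once tension feedback dominates, $t_{R50}$
rises steeply. The overall endpoint contrast (≈ 0.10 s at the lowest
amplitude vs ≈ 0.22 s at full amplitude) is what the mechanism predicts;
strict step-by-step monotonicity holds only in the feedback-dominated
range.

## Parameter estimation

`fit_parameters` estimates $(a, b, C_f, C_s)$ from isometric tension
traces by minimising the pooled mean squared error
$\sum_i (S_{model} - S_{data})^2 / j$ over all $j$ points of all traces,
simulating one twitch per trace length and sampling the model at the
trace's time points. The optimiser is a bounded derivative-free simplex
search (Nelder–Mead on a logistic transform of the box constraints,
default bounds 0.2×–5× the published values): the objective contains an
ODE solve, so finite-difference gradients are unreliable. Candidates
that would make $K_{TnCa0}$ non-positive at any trace length, or whose
simulation fails, receive a large penalty so the simplex can retreat.
During fitting the forward model runs on a 61-point grid with 5 ms
output sampling — discretisation error well below data noise at a
fraction of the cost.

`generate_synthetic_traces` produces experiment-style fixtures: model
twitches sampled every 0.02 s with i.i.d. additive Gaussian noise
(clamped at zero), reproducible per seed. This is a surrogate for
digitisation noise; it emulates the sampling cadence and noise scale of
digitised experimental force traces, but not systematic digitisation
bias, baseline drift, or inter-preparation variability — so parameter
recovery on these fixtures demonstrates identifiability of the model on
its own trajectory family, not robustness to real experimental
artefacts. With the default seven-length fixture set, all four
parameters are recovered to well within 5% from noise-free traces and
10% under 2%-of-peak noise, which is the package's substitute for
refitting the original (unavailable) experimental curves.

## Design choices and limitations

* The force-density relation is read as $\partial S/\partial x = C_f A$:
  force density proportional to occupancy, with no separate shape
  factor.
* Total tension is reported at the z-disk-proximal end of the overlap
  region — the accumulated sum of all cross-bridge forces.
* The grid point nearest the requested position is used when extracting
  local activation traces (`activation_at`); with the default grid the
  z-disk boundary sits at $L_{so}$ itself.
* Isometric only: no shortening, no passive/titin elasticity, no
  double-overlap regime (lengths below ~1.5 µm are rejected), no
  third (weakly bound) cross-bridge state, no dynamic calcium-binding
  kinetics.
* The upslope of tension is effectively length-independent in this
  model, a known simplification of the two-state cycle.
* Problem sizes used throughout the documentation and tests (101 spatial
  samples, 1 ms output, 1 s horizon; 61-point grid inside the fitting
  loop) keep a full twitch at a fraction of a second of compute and a
  full fit at tens of seconds, while all convergence checks pass.
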