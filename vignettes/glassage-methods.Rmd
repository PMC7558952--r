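---
title: "Methods: quantifying physical ageing of glasses by DSC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying physical ageing of glasses by DSC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassage)
```

## The physical picture

An amorphous solid stored at a temperature $T_a$ below its glass transition
$T_g$ is not at equilibrium: its enthalpy slowly relaxes toward the
extrapolated supercooled-liquid line. The enthalpy lost during storage,
$\Delta H_r$, is recovered on reheating as an endothermic overshoot at the
glass transition, which DSC measures. Three connected descriptions of this
process are implemented:

1. **Enthalpy relaxation** (per aged/unaged scan pair):
   $\Delta H_r = \frac{1}{q}\int_{T_1}^{T_2}(\Phi_{aged}-\Phi_{unaged})\,dT
   = \int_{T_1}^{T_2}(C_{p,aged}-C_{p,unaged})\,dT$, bounded by the
   equilibrium value
   $\Delta H_r^\infty = \int_{T_a}^{T_g}\Delta C_p\,dT \approx
   \Delta C_p\,(T_g-T_a)$.
2. **KWW kinetics** (per ageing temperature):
   $\Delta H_r(t) = \Delta H_r^\infty\,[1-\exp\{-(t/\tau)^{\beta}\}]$, with
   the complementary recovery parameter
   $\varphi(t) = \exp\{-(t/\tau)^{\beta}\} = 1-\Delta H_r/\Delta H_r^\infty$.
3. **Fictive temperature**: the temperature at which the glass's structure
   would be the equilibrium liquid structure, obtained either from the
   intersection of the extrapolated liquid and glassy enthalpy lines or by
   the equal-area construction; along an ageing series it maps linearly as
   $T_f(t) = T_g - \Delta H_r(t)/\Delta C_p$.

Kinetic fragility summarises how steeply relaxation slows on cooling:
$E_a = -R\,\mathrm{d}\ln q/\mathrm{d}(1/T)$ from a scan-rate sweep and
$m = E_a/(2.303\,R\,T_g)$, classified here as strong ($m<40$), moderately
fragile ($40\le m<100$) or fragile ($m\ge 100$). The cutoffs are a package
convention: Angell's scheme is qualitative, purely Arrhenius relaxation
corresponds to $m\approx 16$, and typical pharmaceutical glasses fall at
$m = 60$–$120$, so the band places them in the middle class.

## Units and conventions

Internally everything is kelvin, seconds, J g$^{-1}$ K$^{-1}$ and
J g$^{-1}$; Celsius, minutes and hours are accepted only at I/O boundaries
(CSV dialects, YAML configs, printing). Heat flow is endothermic-up; an
exothermic-up instrument is handled by the `endo_up` flag of the CSV
dialect. $T_g$ is reported by the half-$\Delta C_p$ midpoint convention
(the crossing of $C_p$ with $C_{p,solid}+\Delta C_p/2$), with onset/end
from the tangent at the steepest slope. The midpoint is the most common
DSC convention; where a record crosses the half-step line more than once
(a pronounced recovery overshoot), the crossing nearest the steepest slope
is used and a warning is raised.

## Fitting the KWW model

`fit_kww()` minimises the weighted residual sum of squares with
Levenberg-Marquardt iterations in the transformed parameters
$(\ln\tau,\ \mathrm{logit}\,\beta,\ \ln\Delta H_r^\infty)$. The transform
keeps the search well-scaled when $\tau$ ranges from hours to years and
enforces $\beta\in(0,1)$ and positivity without hard constraints. Weights
default to $1/\mathrm{sd}^2$ with a per-point standard deviation of
0.3 J g$^{-1}$ when none is supplied — the typical repeatability of
enthalpy-relaxation measurements.

When ageing times cover only the early, power-law part of the decay
($t\ll\tau$), the three parameters are strongly correlated and the
objective has a long flat valley. Two safeguards are used: a deterministic
multi-start (the half-plateau crossing time plus log-spaced $\tau$ values
between the shortest time and $10^3\times$ the longest, crossed with
$\beta_0\in\{0.3, 0.5, 0.8\}$), and tight convergence tolerances
(`ftol = ptol = 1e-15`). On noiseless model-generated data this recovers
the generating parameters to better than $10^{-6}$ relative even when the
longest ageing time is less than 1% of $\tau$. Parameter covariance is
computed from the analytic Jacobian at the optimum; when the Jacobian is
numerically singular a Moore-Penrose pseudoinverse is substituted so
standard errors remain available (they are then honest but large). The
plateau $\Delta H_r^\infty$ may be fixed from the equilibrium relaxation
(either mode) instead of fitted; the default fits it free, because with
short ageing windows the fitted and thermodynamic plateaus legitimately
differ and forcing agreement would bias $\tau$.

## The area-difference integral

`enthalpy_relaxation()` interpolates both curves linearly onto the union of
their temperature samples inside $[T_1, T_2]$ before trapezoidal
integration. The union grid is exact for piecewise-linear inputs and
introduces no new extrema; it also makes the heat-flow and specific-heat
forms of the integral agree to rounding error, since the rate conversion is
a scalar factor. Default limits are $T_1 = T_g - 40$ K and
$T_2 = T_g + 25$ K, wide enough to bracket the transition and the recovery
overshoot at all simulated ageing levels; they are configurable because
strongly aged glasses push the overshoot to higher temperatures.

## Fictive temperature: two constructions

The intersection method integrates the measured $C_p$ into total enthalpy
(cumulative trapezoid anchored at a reference temperature), fits a straight
glassy-state line below the transition and intersects it with the
extrapolated liquid line. The equal-area method solves
$\int_{T_f}^{T^*}\Delta C_p\,dT = \int_{T'}^{T^*}(C_p - C_{p,solid})\,dT$
by bisection, using the closed-form integral of the linear $\Delta C_p(T)$.
The two are mathematically equivalent when the reference lines are exact
and straight. Note that with temperature-dependent (sloped) baselines the
total enthalpy is curved, and extrapolating straight chord fits biases the
intersection estimate by up to several kelvin over a 40 K extrapolation;
this is a property of the straight-line construction itself, not of the
implementation. For that reason the default synthetic glass uses flat
reference lines (solid 1.2, liquid 1.67 J g$^{-1}$ K$^{-1}$, so
$\Delta C_p = 0.47$), under which both constructions agree to the
integration tolerance and their cross-check is meaningful.

## The TNM synthetic-data generator

Because no public thermogram repository exists for this class of
measurement, all test inputs are generated. The
Tool-Narayanaswamy-Moynihan model evolves the fictive temperature through
an arbitrary cool/hold/heat program via the discretised KWW superposition

$$T_f(t_n) = T_0 + \sum_j \Delta T_j\Big[1-\exp\Big\{-\Big(
  \sum_{k=j}^{n}\Delta t_k/\tau_k\Big)^{\beta}\Big\}\Big],\qquad
  \ln\tau_k = \ln A + \frac{x\,\Delta h^*}{R T_k}
  + \frac{(1-x)\,\Delta h^*}{R T_{f,k-1}},$$

and reports the measurable $C_p = C_{p,solid} + \Delta C_p\,dT_f/dT$ on
ramps. Reduced time is accumulated once per step and only steps with a
temperature change contribute superposition terms, so a
cool–hold(32 h)–cool–reheat protocol costs a few thousand steps and runs in
well under a second. Ramps are stepped at $\le 0.5$ K (automatically
subdivided; with `subdivide = FALSE` a coarser request is a hard error) and
holds at `dt = 60` s by default.

The default glass — $\Delta h^* = 500$ kJ mol$^{-1}$, $x = 0.5$,
$\beta = 0.5$, $\ln A$ set so $\tau(375.35\,\mathrm{K}) = 100$ s — is a
deliberate idealisation of a small-molecule drug glass with
$T_g \approx 102$ °C at 10 K min$^{-1}$ and a fragility in the moderately
fragile band. The 100 s convention ties the nominal $T_g$ to the standard
scan rate. The generator reproduces the phenomena the analysis needs:
overshoots that grow and shift upward with ageing time, rate-dependent
$T_g$/$T_f$, enthalpy conservation between the hold and the reheat
overshoot (checked to 5%), and $T_f$ decreasing from $T_g$ toward $T_a$
with ageing. It does **not** emulate instrument smearing, baseline
curvature or drift, partial vitrification when $T_a$ lies inside a broad
transition, or chemical degradation — so green tests certify the analysis
chain, not robustness to every instrumental artefact of real thermograms.
Phenomenological aged/unaged pairs (sigmoid step plus Gaussian peak of
exactly known area) complement the TNM curves where bit-exact ground truth
for the area integral is wanted, and `simulate_kww_series()` provides
seeded noisy series for the kinetics layer.

## The fragility sweep protocol

Cooling sweeps use the limiting fictive temperature of each run; heating
sweeps use the midpoint $T_g$. For heating, the package's default protocol
cools at the *same* rate as the subsequent heating leg (the classical
equal-rate protocol). This choice matters: in the TNM model the midpoint
shift of heating scans after a *fixed* pre-cool rate reflects a mixture of
the glass formed by the pre-cool and the heating kinetics, and its slope
does not estimate $\Delta h^*$ (numerically it overestimates it by tens of
percent), whereas under matched rates the heating $T_g$ tracks the cooling
$T_f$ and both branches recover $E_a \approx \Delta h^*$. A `fixed_cool`
option reproduces the instrument-style protocol for users who want it,
with the caveat above. The reference $T_g$ for $m$ is the characteristic
temperature at the rate nearest the standard 10 K min$^{-1}$.

One related interpretation choice: "the fictive temperature of the unaged
glass equals the glass transition temperature" is checked against the
*nominal* $T_g$ of the simulated material (the $\tau = 100$ s temperature,
375.35 K). The heating-scan midpoint itself sits a few kelvin above the
frozen-in $T_f$ — ordinary scan hysteresis, largest at small $\beta$ — so
midpoint-vs-$T_f$ is asserted only directionally (midpoint above, gap
bounded), not as an equality.

## Numerical choices and degenerate inputs

- Integration is trapezoidal on the sampled grid with no default
  smoothing; enthalpy integration agrees with a fine Riemann sum to
  $10^{-6}$ relative in the tests.
- Program/record matching in `segment_curve()` tolerates 2 K of
  instrument lag, configurable.
- Equal-length solid/liquid baseline lines that cross anywhere in the
  transition gap are rejected; an exactly zero step is allowed with a
  warning (it arises when calibrating both windows on one straight line).
- Replicated ageing times are averaged with pooled standard deviations
  before fitting; measured $\Delta H_r$ slightly below zero (down to
  $-0.3$ J g$^{-1}$) is accepted as noise around zero.
- All generators are deterministic under a seed; study reports contain no
  timestamps, so a fixed seed reproduces byte-identical JSON.

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
data: relaxation series of 8 ageing times (30 min–32 h), TNM simulations
of 500–3000 steps per program, rate sweeps of 5–6 rates per mode, and a
200-replicate Monte-Carlo check of fit robustness at noise
sd = 0.3 J g$^{-1}$. These sizes mirror the scale of a real DSC ageing
campaign (a handful of ageing times and rates per temperature) while
keeping the full suite fast.

## Limitations

- The KWW plateau and the thermodynamic equilibrium relaxation are related
  but distinct estimands; with ageing windows much shorter than $\tau$ the
  fitted plateau carries large uncertainty, which the reported covariance
  makes explicit.
- Fictive-temperature estimation with sloped baselines inherits the
  straight-line extrapolation bias discussed above; users fitting real
  data with visibly sloped baselines should prefer the equal-area method.
- The TNM simulator is forward-only; fitting TNM parameters to measured
  thermograms is out of scope.
- No correction is attempted when the ageing temperature lies inside a
  broad glass transition (partial vitrification), a regime real
  measurements can encounter just below $T_g$.
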