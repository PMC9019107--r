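---
title: "Quantifying wind-turbine avoidance from GPS tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wind-turbine avoidance from GPS tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbavoid)
```

## The scientific question

Soaring birds collide with wind-turbine rotor blades, and the behavioural
mechanisms behind (non-)avoidance are poorly understood. Given GPS tracks of
birds moving through a turbine landscape — positions, flight heights, ground
speeds and headings — `turbavoid` asks whether birds orient *towards* the
nearest turbine less often than chance would predict, and which conditions
modulate that avoidance.

The core statistic is deliberately simple. For each fix, compute the bearing
from the bird to its nearest turbine and the angular deviation of the
recorded flight heading from that bearing. The binomial response is

$$y_i = \mathbf{1}\{\,|\,\mathrm{heading}_i - \mathrm{bearing}_i\,|_{\circ} < 60^\circ\},$$

with $|\cdot|_\circ$ the minimal circular difference. If birds choose
directions at random, the 120° facing cone out of 360° gives
$\Pr(y_i = 1) = 1/3$; deviations below one-third indicate active avoidance
of trajectories that would lead into the rotor-swept zone. The 60° boundary
is strict (`deviation < 60`): turning angles of 60–90° are the signature of
birds actively steering away, and they belong in the non-facing class.

## The two models

**Distance model (GAMM).** At the landscape scale (fixes within 1500 m of a
turbine) facing probability is modelled as

$$\mathrm{logit}\,\Pr(y_{bi}=1) = \beta_{c(i)} + f_{c(i)}(d_i) + u_b,
\qquad u_b \sim N(0, \sigma_b^2),$$

with $d_i$ the distance to the nearest turbine, $c(i)$ a flight-height class
and $u_b$ a per-bird random intercept. Height classes are defined relative
to the *maximum turbine height* $H$ (hub height plus rotor radius; when the
hub height is unknown, $1.5\times$ rotor diameter, a good approximation for
common turbine models whose hub height roughly equals rotor diameter):
**low** ($h \le H$, the rotor-swept zone and below), **medium**
($H < h \le 2H$) and **high** ($h > 2H$). Both class boundaries are
inclusive on the low side, matching the "up to" reading of the class
definitions. The interesting contrast is that avoidance should appear only
in the low class — birds flying above the rotors have no reason to deviate.

**Near-turbine model (GLMM).** Within the zone of influence (fixes within
750 m *and* in the low class), a logistic mixed model asks what modulates
avoidance: bird age and sex, the signed wind component blowing towards the
nearest turbine, and the uplift environment at the turbine's location.
Turbine height and thermal uplift are too collinear to share a model (tall
turbines stand where surface heating differs systematically), so two
configurations are fitted: one with thermal uplift, one with turbine
height. The package refuses any configuration containing a predictor pair
with $|r| > 0.7$.

The wind covariate is the scalar projection of the wind vector onto the
bird-to-turbine bearing, in m/s, positive when the wind pushes the bird
toward the turbine. Wind direction inputs use the meteorological convention
(direction the wind blows *from*, as weather stations report); the package
adds 180° internally. A negative coefficient means birds avoid facing
turbines more strongly when the wind would drag them into the rotors.

## Covariate engineering

- **Orographic uplift**: $w_o = v\,\sin(s)\,\max(0, \cos(a - \phi))$, with
  wind speed $v$, terrain slope $s$, aspect $a$ (downslope-facing compass
  direction) and meteorological wind direction $\phi$. Zero on flat ground
  and on lee slopes; bounded by the wind speed. Terrain derivatives come
  from Horn's eight-neighbour finite differences on an elevation grid;
  border cells are flagged invalid.
- **Thermal uplift**: the convective velocity scale
  $w^* = (g\, z_i\, \Delta T / T_{\mathrm{ref}})^{1/3}$ with
  $\Delta T = \max(0, T_s - T_{\mathrm{ref}})$, boundary-layer depth
  $z_i = 1000$ m by default, and $T_{\mathrm{ref}}$ the domain-mean surface
  temperature. Thermal uplift is treated as static per grid cell: in the
  study season (summer, midday) the spatial pattern of surface heating is
  far more variable than its temporal fluctuation.
- Both uplift layers live on a 500 m grid and are evaluated **at the
  nearest turbine's cell**, not at the bird's position — the question is
  whether the uplift environment *around the turbine* attracts risky
  flight. Rotor-wake turbulence is explicitly not modelled.
- **Wind matching** is nearest-in-time against the 10-minute station
  record, ties toward the earlier record; a match staler than 60 minutes
  flags the fix as covariate-missing and it is excluded listwise from model
  subsets.

## Filtering

Three filters precede analysis, and a `filter_report` proves conservation
(`dropped + retained = input`) at every stage:

1. **Not flying**: ground speed < 1 m/s (perched birds have headings but no
   trajectory).
2. **1 Hz bursts**: fixes closer than 5 s to the previously retained fix of
   the same bird are dropped (greedy thinning). High-frequency bursts
   otherwise dominate the data with serially dependent near-duplicates;
   removing them is what renders model residuals approximately
   uncorrelated, and the `temporal_acf()` diagnostic exists to verify
   exactly that. The 5 s threshold cleanly separates 1 Hz bursts from 10 s
   and slower schedules.
3. **Distance**: beyond 1500 m (GAMM) / 750 m (GLMM) of the nearest
   turbine; both cut-offs inclusive.

## Fitting choices

The GAMM is fitted with `mgcv::gam`: cubic B-splines of distance (basis
dimension 10 per class, second-order difference penalty), one smooth per
height class (factor-`by` structure) plus the class main effects, and the
bird intercept as an `s(bird_id, bs = "re")` variance component. Smoothing
parameters are selected by REML with the effective-degrees-of-freedom
penalty inflated to `gamma = 6`. This deliberately conservative selection is
a specificity choice: the scientific readout of the model is *which height
classes carry a real distance effect*, so a class with no effect should be
reported as flat (EDF ≈ 1, as a practitioner reads "no effect" in a smooth
table) rather than absorbing sampling noise into spurious wiggliness, which
plain REML does in a substantial fraction of null datasets. The cost is
that genuine fine structure is smoothed harder; with the strong low-class
signal this changes the EDF, not the conclusion. The per-class Wald-type
$\chi^2$ tests on the penalized coefficients are approximate, as usual.

Smooth p-values, partial-effect curves (95% pointwise Wald bands on the
link scale, transformed to probabilities, random intercept excluded — an
"average bird") and the random-intercept SD are returned in a `facing_gamm`
object. Prediction outside the fitted distance range is refused; splines do
not extrapolate.

The GLMM is `lme4::glmer` (Laplace approximation), predictors on their raw
scales, Wald $z$, $p$ and $\pm 1.96\,\mathrm{SE}$ intervals.
Nakagawa–Schielzeth $R^2$ uses the theoretical logit-link method:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_b + \pi^2/3)$ and
$R^2_c = (\sigma^2_f + \sigma^2_b) / (\sigma^2_f + \sigma^2_b + \pi^2/3)$,
with $\sigma^2_f$ the variance of the fixed-effect linear predictor over
the data.

**Cross-validation** is observation-level ten-fold by default (the data are
split at random, so one bird's fixes can appear in training and test; the
bird-level alternative sits behind `by_bird = TRUE`). Predictions classify
facing at 0.5; birds unseen in a training fold are predicted with a random
intercept of zero. A fold randomization that leaves a training set with
only one response class is re-drawn (at most five times, logged). Accuracy
is reported as mean ± SD percent correct over folds. Note the base-rate
behaviour: with facing prevalence 1/3 and no usable signal, always
predicting "not facing" scores ~67%, so accuracy must be read against that
baseline, not 50%.

**Diagnostics** mirror the residual checks a careful analysis needs:
per-bird temporal ACF (lags in fix index, weighted average across birds,
±1.96/√n envelope) and a Moran-type distance-binned spatial correlogram
with envelopes from 199 residual permutations. Bins with fewer than 30
pairs are flagged. The correlogram is O(n²) in fixes; subsample a few
thousand residuals for routine use.

## The synthetic generator

Because the real tracking data cannot ship with the package, every stage is
validated against a generator whose truth is known. `scenario_config()`
fixes the scenario; `simulate_scenario()` produces turbines in ridge rows,
a 10-minute von Mises/Gamma wind regime, a 500 m terrain grid (ridge slope
under the rows, facing the prevailing wind; smooth surface-temperature
field) and bird tracks. Per fix, the generative facing logit is

$$\eta = \eta_0 + u_b
 - \delta\,\mathrm{invlogit}\!\left(\frac{d_0 - d}{s}\right)\mathbf{1}[\mathrm{low}]
 + \beta_w\, w_c\, \mathbf{1}[\mathrm{low},\, d \le d_0],$$

with defaults $\eta_0 = \mathrm{logit}(1/3)$ (the random-orientation null
far from turbines), avoidance depth $\delta = 2$ ramping in logistically
around $d_0 = 750$ m with shape $s = 150$ m (facing probability near
turbines ≈ 0.06, recovering toward 1/3 past 1000 m), wind slope
$\beta_w = -0.06$ per m/s (the magnitude reported for this study system),
and per-bird intercept SD $\sigma_b = 0.2$ (chosen to reproduce the small
conditional-vs-marginal $R^2$ gap the near-turbine models show). Facing is
drawn Bernoulli; the heading is then drawn uniformly inside the ±60° cone
or uniformly over its complement — deliberately no finer angular structure,
so the facing indicator is sufficient. The bird advances along its heading
at 6–14 m/s plus half the wind vector, reflecting at the box boundary.
Heights are drawn per fix from a low/medium/high mixture relative to the
nearest turbine's height, so every class spans its bracket. Consecutive
birds start an hour apart, as in a real campaign where individuals are
tracked across different parts of the wind record.

The generator computes distance, bearing, wind component and height class
with the *same primitives* the annotation pipeline uses, so
generator-annotator agreement is exact and testable to 1e-6 — and the
GLMM's linear predictor on the low/≤750 m subset is exactly the generative
logit restricted to the fitted terms, making recovery tests meaningful.
Two scenario conventions follow from this identifiability requirement:

- *Wind-recovery and type-I scenarios set* $\delta = 0$. With the distance
  ramp active, wind drift correlates the wind component with the (unfitted)
  ramp — birds pushed toward turbines sit deeper in it — and the GLMM,
  which by design contains no distance term, absorbs that confound into the
  wind slope. The ramp is the GAMM's recovery target; the wind slope is the
  GLMM's. Each is tested where it is identified.
- *Near-turbine scenarios use 1-minute fixes* (`step_interval = 60`), the
  study's mid-day logging regime, so each bird's track spans many
  10-minute wind records and the uplift covariates vary within birds. At
  10 s fixes a whole track sees two wind records and cluster-level Wald
  inertia distorts calibration.

What the generator does **not** emulate: thermalling circles and soaring
kinematics, attraction to uplift, collision events, turbine wakes, and any
dependence of the heading distribution on covariates beyond the facing
indicator. Passing recovery tests therefore demonstrates the estimators are
correct for the facing process; it does not validate movement realism.

## Default problem sizes

The default scenario is 80 birds × 220 fixes (≈ 10–16k analyzed locations
after filtering), the magnitude of the study system's real modelling
dataset (13,682 locations from 126 birds). Validation runs use: 20
replicates of 100 birds × 150 fixes for wind-slope recovery; 50 replicates
of the default scenario for GAMM shape recovery; 100 replicates of 100
birds × 80 one-minute fixes for type-I calibration. The random-orientation
null uses 100,000 Monte-Carlo headings.

## Numerical conventions and degenerate inputs

- All interfaces use degrees (headings, bearings, aspects, wind
  directions); radians only inside function bodies. Distances and bearings
  are spherical (haversine / initial bearing, R = 6,371 km): at ≤ 1.5 km
  range the spherical-vs-projected discrepancy is far below GPS noise, and
  no projection dependency is needed.
- Heights are *above ground*; converting GPS altitude to AGL is the data
  supplier's responsibility. Negative AGL (GPS error) is clamped into the
  low class and counted, not dropped.
- Nearest-turbine ties (within 1 nm) resolve to the lexicographically
  smallest turbine id; wind-match ties resolve to the earlier record.
- Single-bird data drop the random intercept with a warning (variance
  reported 0); single-class data fit only that class's smooth; constant
  predictors are refused as rank-deficient with the term named.
- Every run is a pure function of (inputs, seed): seeded simulations,
  fold assignments and permutation envelopes reproduce byte-identically,
  and CLI outputs embed a config hash but no timestamps.

## Known limitations

- Temporal ACF lags are fix-index, not wall-clock; mixed logging schedules
  blur the lag scale.
- The spatial correlogram's permutation null assumes exchangeable
  residuals; strong covariate gradients can widen true envelopes.
- The GLMM treats fixes as conditionally independent given the bird; the
  thinning filter is the only concession to serial dependence, mirroring
  the diagnose-and-thin strategy rather than fitting correlation
  structures.
- Uplift formulas are deliberately simple surface models; they are
  covariate proxies, not micrometeorology.
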