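# turbavoid

Quantifying wind-turbine avoidance behaviour from GPS tracking of soaring
birds.

## The problem

Soaring raptors die in collisions with wind-turbine rotor blades, yet some
species show far lower collision rates than their abundance near wind farms
would predict. One behavioural explanation is *directional avoidance*: birds
recognize turbines and stop orienting towards them as they approach, at
least when flying low enough to be at risk. `turbavoid` implements the full
analysis chain for testing this hypothesis from telemetry data, for movement
ecologists and wind-farm impact assessors.

The central statistic is the **facing indicator**: a GPS fix scores 1 when
the bird's flight heading deviates by less than 60° from the bearing to the
nearest turbine, 0 otherwise. Under random flight directions the expected
facing proportion is 120/360 = **1/3** (and 2/3 non-facing), so depressions
below one-third measure avoidance. Two mixed models interrogate the
response:

- a binomial **GAMM**,
  `logit P(facing) = β_class + f_class(distance) + u_bird`, with a separate
  penalized spline of distance to the nearest turbine for each
  flight-height class (low: up to the maximum turbine height `H` = hub +
  rotor radius, or 1.5 × rotor diameter when the hub height is unknown;
  medium: up to `2H`; high: above) and a per-bird random intercept, fitted
  to fixes within 1500 m;
- a binomial **GLMM** on the near-turbine subset (≤ 750 m, low height) with
  age, sex, the signed wind component blowing towards the turbine (m/s),
  and orographic/thermal uplift at the turbine's location as fixed effects
  — fitted in two configurations because turbine height and thermal uplift
  are collinear.

Supporting machinery: Movebank-dialect CSV I/O, speed/burst filtering with
count-conserving reports, nearest-turbine annotation, Horn terrain
derivatives and uplift covariates, Nakagawa–Schielzeth R², ten-fold
cross-validated accuracy, temporal-ACF and spatial-correlogram residual
diagnostics, and a synthetic track generator with known avoidance
parameters that lets every estimator be validated by parameter recovery.

## Worked example

Simulate a small scenario with known behaviour (avoidance depth 2 on the
logit scale inside 750 m, wind-component slope −0.06 per m/s, per-bird
intercept SD 0.2), run the annotation pipeline, and fit both models:

```r
library(turbavoid)

cfg <- scenario_config(n_birds = 25, steps_per_bird = 220, seed = 42)
scn <- simulate_scenario(cfg)

flying  <- filter_flying(scn$tracks)
thinned <- exclude_high_frequency(flying$tracks)
ann     <- annotate_tracks(thinned$tracks, scn$turbines, scn$wind, scn$terrain)

fit <- fit_facing_gamm(subset_gamm(ann))
print(fit)
```

```
Binomial facing-probability GAMM (3540 fixes, 25 birds)
Distance smooths by flight-height class:
  height_class edf chi_sq p_value
1          low   1  59.26   0.000
2       medium   1   1.42   0.234
3         high   1   2.61   0.106
Bird random-intercept SD: 0.000619
```

The low-class smooth is strongly significant while the medium and high
classes are flat (EDF ≈ 1): birds below rotor height stop facing turbines
as they approach, birds above do not react. The partial-effect curve
quantifies the dip — here the fitted facing probability at 200 m versus
1400 m for an average bird:

```r
predict_partial_effect(fit, "low", c(200, 1400))
```

```
  distance       prob      lower     upper
1      200 0.08837951 0.06310353 0.1224564
2     1400 0.33770538 0.30880274 0.3678734
```

far below the 1/3 null near the turbine and back at it far away. The
near-turbine GLMM estimates the wind effect:

```r
glmm <- fit_facing_glmm(subset_glmm(ann), config = "with_thermal")
print(glmm)
```

```
Binomial facing-probability GLMM (with_thermal; 342 fixes, 14 birds)
               term estimate     se      z  lower   upper p_value
1       (Intercept)   -0.925 0.5869 -1.576 -2.075  0.2251  0.1149
2            agejuv   -0.566 0.4613 -1.227 -1.470  0.3382  0.2198
3              sexm   -0.203 0.4027 -0.505 -0.993  0.5859  0.6135
4    wind_component   -0.126 0.0519 -2.418 -0.227 -0.0238  0.0156
5 orographic_uplift   -0.484 0.3702 -1.306 -1.209  0.2420  0.1914
6    thermal_uplift   -0.124 0.0781 -1.584 -0.277  0.0294  0.1132
Bird random-intercept variance: 0
Nakagawa R2 marginal/conditional: 0.12 / 0.12
```

The `wind_component` estimate is negative and significant — birds avoid
facing the turbine hardest when the wind would push them into it — and its
confidence interval covers the generative slope of −0.06. With only 342
near-turbine fixes from this toy scenario the point estimate is noisy (and
the active avoidance ramp leaks into it; see the vignette); the acceptance
suite demonstrates unbiased recovery across 20 replicates at the study's
scale. The other predictors have no generative effect and show none. The R²
line uses the Nakagawa–Schielzeth theoretical method.

A command-line interface covers the same pipeline
(`simulate | annotate | fit-gamm | fit-glmm | cv | diagnose | report`):

```sh
Rscript inst/scripts/turbavoid simulate --seed 42 --out-dir scenario/
Rscript inst/scripts/turbavoid annotate --tracks scenario/tracks.csv \
    --turbines scenario/turbines.csv --wind scenario/wind.csv \
    --terrain scenario/terrain.csv --out annotated.csv --report report.json
Rscript inst/scripts/turbavoid fit-glmm --annotated annotated.csv --out glmm.json
```

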