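# codameta

Compositional meta-analysis of 24-hour movement behaviors and adiposity.

## The problem

A child's day is a closed budget: minutes spent sleeping, sedentary, in
light-intensity physical activity (LPA) or in moderate-to-vigorous
physical activity (MVPA) sum to 1440. Associations between any one
behavior and an adiposity outcome (BMI z-score, waist circumference,
body-fat percentage, fat-mass index) are therefore only interpretable
*relative to* the remaining behaviors. Compositional data analysis makes
this explicit: the 4-part composition `(x_sleep, x_sed, x_lpa, x_mvpa)`
is mapped to pivot (isometric log-ratio) coordinates, where the first
coordinate isolates one behavior against the geometric mean of the rest,

```
z1 = sqrt(3/4) * ln( x_b / ( prod_{j != b} x_j )^(1/3) )
```

and a linear model of the outcome on `(z1, z2, z3)` yields, per behavior
`b`, a coefficient `beta1` for "more of `b` relative to everything else".

`codameta` meta-analyzes such coefficients across studies. For a study
with mean composition `x` and a reallocation of `d` minutes into
behavior `b` (all other behaviors shrinking proportionally — an
*all-for-one* substitution), the first coordinate changes by

```
dz1(d) = sqrt(3/4) * ln( (x_b + d)(T - x_b) / ( x_b (T - x_b - d) ) ),   T = 1440
```

so the predicted absolute outcome change is `beta1 * dz1(d)` with
variance `dz1(d)^2 * SE(beta1)^2` (log-scale outcomes are
back-transformed through the study mean by the delta method). Per
(outcome, behavior, reallocation) these effects are pooled with a
generic inverse-variance random-effects model, `tau^2` estimated by
REML, heterogeneity summarized by `I^2`, and moderation by study mean
age probed with a restricted-cubic-spline meta-regression (3 knots at
ages 5, 10, 15 years; 2 moderator degrees of freedom).

The package is aimed at researchers synthesizing published
time-use-composition studies of children and adolescents, and at
methodologists who need a truth-known simulation bench for this class of
pipelines: the bundled generator draws logistic-normal compositions,
simulates per-study individual data, re-fits coefficients, encodes their
uncertainty as SEs, confidence intervals or p-values, and retains every
generating parameter for recovery scoring.

## Worked example

```r
library(codameta)

# a truth-known corpus: 30 studies of n = 500, moderate heterogeneity
truth <- synthetic_truth(seed = 1)
corp  <- simulate_corpus(truth)

# pooled change in zBMI for 30 more minutes of MVPA per day
dose_response(corp$records, "mvpa", "zbmi", grid = c(30, 60))
#>   outcome_name behavior delta_min  k pooled_estimate   pooled_se     ci_low    ci_high   z_value       p_value
#> 1         zbmi     mvpa        30 30      -0.1209936 0.004637164 -0.1300823 -0.1119049 -26.09215 4.475722e-150
#> 2         zbmi     mvpa        60 30      -0.2077456 0.007945047 -0.2233176 -0.1921736 -26.14782 1.043545e-150
#>           tau2       i2     i2_q   q_stat q_df
#> 1 0.0001386790 21.51771 21.90323 37.13342   29
#> 2 0.0004009105 21.19041 21.56691 36.97419   29
```

Spending 30 more minutes/day in MVPA relative to the remaining
behaviors is associated with a 0.12-unit lower BMI z-score in this
simulated corpus (95% CI −0.130 to −0.112), with modest between-study
heterogeneity (I² ≈ 22%); the generating truth for the 30-minute effect
is −0.125, inside the interval. The full pipeline — validation, effect
curves over ±10..60 min, pooling, and the age/quality meta-regressions —
runs from one call:

```r
cfg <- pipeline_config(corp$records, output_dir = "out", seed = 1)
run_pipeline(cfg)   # writes effects.csv, pooled.csv, metareg.csv, ...
```

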