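---
title: "Pooling time-use composition effects: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling time-use composition effects: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codameta)
```

## The model

A day is a 4-part composition `x = (x_sleep, x_sed, x_lpa, x_mvpa)`
closed to `T = 1440` minutes. All analysis happens in pivot (isometric
log-ratio) coordinates. For pivot behavior `b` the parts are reordered
with `b` first (the other three keep their canonical order), and

$$z_j = \sqrt{\tfrac{D-j}{D-j+1}}\,
        \ln\frac{x_j}{\big(\prod_{l>j} x_l\big)^{1/(D-j)}},
        \qquad D = 4,\; j = 1,2,3,$$

so that $z_1 = \sqrt{3/4}\,\ln\!\big(x_b / g(x_{-b})\big)$ contrasts the
pivot against the geometric mean of the rest. The normalizing constant
$\sqrt{(D-1)/D}$ is the standard orthonormal choice; with it, the four
pivot bases are orthogonal rotations of one another, which is what makes
per-behavior coefficients mutually consistent (each rotation's
coefficient vector is an exact linear image of any other's —
`fit_study()` exploits nothing, but the tests verify it).

**Per-study model.** Each study regresses its outcome on
$(z_1,z_2,z_3)$, an intercept and covariates by OLS; the coefficient
$\beta_1^{(b)}$ on the first coordinate, repeated with each behavior as
pivot, is the study's contribution. Standard errors use homoskedastic
residual variance on $n-p$ degrees of freedom, matching the linear-model
output that published studies report.

**Reallocation effect sizes.** The all-for-one substitution adds $d$
minutes to the target while the remaining parts shrink proportionally,
preserving their subcomposition. Because only the first coordinate
moves in a direction confounded with the target, the predicted change
in the outcome is $\beta_1 \Delta z_1(d)$ with
$\Delta z_1(d) = \sqrt{3/4}\,\ln\big[(x_b+d)(T-x_b)\big] -
\sqrt{3/4}\,\ln\big[x_b(T-x_b-d)\big]$, and its variance is
$\Delta z_1(d)^2 \mathrm{SE}(\beta_1)^2$ — the study's mean composition
is treated as fixed, so only coefficient uncertainty propagates.
Outcomes modeled on the log scale are back-transformed through the
study mean $\bar y$: estimate $\bar y(e^{\beta_1\Delta z_1}-1)$,
delta-method variance
$(\bar y\, e^{\beta_1\Delta z_1} \Delta z_1\, \mathrm{SE})^2$. Reported
uncertainty is accepted as exactly one of SE, 95% CI (SE = width /
$2z_{0.975}$) or an exact two-sided p-value (SE = $|\beta_1|/z_{1-p/2}$;
a t-quantile alternative with $n-5$ df is available, normal is the
default since the source analyses report Wald z statistics).
Inequality-censored p-values ("<0.001") are rejected rather than
converted: any conversion would fabricate precision.

**Pooling.** Per (outcome, behavior, $d$), effects are combined by
generic inverse-variance random-effects meta-analysis: weights
$1/(v_i+\tau^2)$ with $\tau^2$ maximizing the restricted likelihood of
$y_i \sim N(\mu, v_i+\tau^2)$, Wald inference
($z = \hat\mu/\mathrm{SE}$, normal CI — not Knapp–Hartung, to match
z-type reporting), and
$I^2 = 100\,\tau^2/(\tau^2+\tilde v)$ with Higgins' typical within-study
variance $\tilde v = (k-1)\sum w_i / \big[(\sum w_i)^2-\sum w_i^2\big]$
from fixed-effect weights; the Q-based $I^2$ is carried as a secondary
column. Pooling requires at least two studies; pooling is done
independently at each grid point because $\Delta z_1$ is nonlinear in
$d$ and study compositions differ, so no single-point rescaling is
exact. Multiple samples from one study enter as independent effects (no
cluster-robust adjustment — a known limitation).

**Age moderation.** The 30-minute effects are regressed on study mean
age through a restricted cubic spline with knots at 5, 10 and 15 years
(Harrell's truncated-power form, nonlinear column scaled by
$(k_3-k_1)^2$; 3 knots give exactly 2 moderator columns). The fit is the
mixed-effects meta-regression $y_i \sim N(X_i\gamma, v_i+\tau^2)$ under
REML; the moderator test is the Wald chi-square on the two spline
coefficients (df = 2), consistent with conventional Q-test reporting.
Study quality ratings enter the same machinery as a single linear
column. Meta-regression is gated at 10 effect estimates.

## Numerical choices

* REML maximization is bounded scalar optimization of the profiled
  restricted log-likelihood on $\tau^2 \in [0,\ 10\,\mathrm{var}(y)]$
  (tolerance 1e-10), with the $\tau^2 = 0$ boundary checked explicitly;
  ties at the boundary return 0. The tests require agreement with an
  independent two-stage grid search to 1e-6 and with `metafor`'s Fisher
  scoring to its own convergence limit.
* Compositions are validated strictly positive; zeros are rejected, not
  imputed (zero-replacement is out of scope). Printed geometric-mean
  compositions rarely sum to 1440 — they are closed (rescaled) on input,
  with a message.
* Reallocations are range-checked: $d$ must keep the target and the
  remainder strictly positive. In pooled curves an infeasible $d$ drops
  that study from that grid point only (relevant for MVPA decreases:
  several plausible study means are below 60 min/day).
* $\Delta z_1$ is strictly increasing in $d$ and concave **while the
  target stays below half the day** ($x_b + d < 720$ min); the curvature
  $-1/(x_b+d)^2 + 1/(T-x_b-d)^2$ changes sign at $T/2$. Every realistic
  grid lives in the concave region, and the property tests restrict to
  it. One consequence worth knowing when reading dose-response figures:
  removing $d$ minutes moves $z_1$ further than adding $d$ does, so
  curves are steeper on the decrease side.
* Tabular outputs serialize numbers at 10 significant digits, making
  pipeline reruns byte-identical.

## What the synthetic generator emulates

`synthetic_truth()` fixes the generating conditions; `simulate_corpus()`
realizes them. Individual compositions are logistic-normal: trivariate
normal pivot coordinates around the center composition, inverted to
minutes — guaranteeing valid compositions and matching the geometry the
analysis assumes. Defaults, chosen once as a realistic childhood-cohort
scenario:

* center 539/525/320/57 min (sleep/sedentary/LPA/MVPA) — the printed
  geometric means of a large multi-country cohort of 9–11-year-olds,
  closed to 1440;
* coordinate SDs 0.10/0.15/0.35 — sleep ratios vary least across
  children, the LPA/MVPA balance most;
* coefficient vector $(-0.45, 0.40, 0.35)$ in sleep-pivot coordinates,
  implying per-behavior $\beta_1$ of −0.45 (sleep), +0.53 (sedentary),
  +0.25 (LPA), −0.32 (MVPA): the sign pattern reported for adiposity
  outcomes, with a 60-minute MVPA reallocation worth about −0.21 zBMI;
* residual SD 0.25 so that $\mathrm{SE}(\beta_1) \approx 0.1$ at the
  default n = 500; K = 30 studies; study mean ages uniform on [3, 18];
  quality ratings uniform on [55, 95]%.

Between-study heterogeneity is an isotropic $N(0,\tau^2 I_3)$
perturbation of the coordinate coefficient vector, drawn once per
study. Because the rotation to any pivot is orthogonal, this induces SD
exactly $\tau$ on every behavior's first-coordinate coefficient — the
scale the meta-analysis estimates. Age effects multiply the coefficient
vector: `flat` (none), `linear`, or `window(a_low, a_high, attenuation)`
— full effect inside the age window, attenuated outside. Uncertainty is
encoded per study × behavior as SE, CI or exact p with configurable
mixing, and the fitted SEs are withheld in the truth sidecar so the
decoding paths can be scored.

What it does *not* emulate: accelerometer measurement (epochs,
wear-time, cut-point misclassification of LPA), covariate confounding,
non-normal outcomes, reporting or publication bias, and correlated
effects from shared samples. Passing recovery tests therefore certify
the statistical pipeline, not robustness to measurement artifacts in
real corpora.

## Validation designs

Problem sizes were chosen so each check is informative at desk scale:

* **End-to-end recovery.** 400 homogeneous corpora ($\tau = 0$, K = 30,
  n = 500) through the full simulate → fit → encode → decode → pool
  chain; the pooled 30-minute MVPA effect must be unbiased within 2
  Monte-Carlo SEs with 95% CI coverage in [92.5%, 97.5%].
* **Moderator calibration.** The spline Q test's size is estimated on
  1000 corpora drawn directly from the meta-regression's own sampling
  model $y_i \sim N(-0.1, v_i + 0.05^2)$, K = 100, SE ~ U(0.06, 0.14):
  the fitted model only ever sees (effect, variance, age), so
  effect-level simulation exercises exactly the tested component at a
  fraction of the cost of individual-level corpora. Rejection must fall
  in the 99% binomial band around 5% (3.6–6.6%).
* **Window recovery.** Truth: effect −0.40 for ages 6–13, zero outside
  (K = 40, SE 0.10, $\tau = 0.05$). The fitted curve must be
  significantly negative at ages 8, 10, 12 and non-significant at 4 and
  16 in >80% of 200 replicates. The outside probes sit at 4 and 16
  rather than the extreme ends of the age range deliberately: a 2-df
  restricted spline cannot represent a step, so its weighted-LS
  projection near the extrapolation boundary is nonzero *by
  construction* — a property of the basis, not an estimation failure.
* **Heterogeneity oracle.** REML $\hat\tau^2$ against grid search on 50
  small meta-datasets (k = 3–10), and consistency within 20% of truth
  at k = 200.

## Known limitations

Effects from the same study are pooled as independent; no
publication-bias diagnostics or prediction intervals; one-for-one
(pairwise) substitutions, compositions with more than four parts and
zero-replacement are out of scope; the quality moderator is assumed
linear. The spline meta-regression extrapolates linearly beyond ages 5
and 15 — interpret curve tails with the widened bands, not the point
estimates.
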