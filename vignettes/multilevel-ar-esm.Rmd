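---
title: "Deciding between two- and three-level AR(1) models for experience sampling data"
author: "esmar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding between two- and three-level AR(1) models for experience sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Experience sampling (ESM) studies prompt participants several times a day
("beeps") across many days, yielding intensive longitudinal data nested as
beeps within days within persons. Affect-dynamics research usually fits a
*two-level* multilevel AR(1) model — occasions within persons — and reads
the autoregressive coefficient as *emotional inertia*, the carry-over of
affect from one moment to the next. But the day is a plausible intermediate
level: daily means may fluctuate, and carry-over may also operate from day
to day. Misjudging the number of levels is not a cosmetic error. Day-level
variance that a two-level AR model cannot represent is absorbed into the
inertia estimate, inflating it (entire good or bad days masquerade as
moment-to-moment carry-over); conversely, a three-level model applied to
genuinely two-level AR data manufactures spurious day-level variance and
deflates the beep-level inertia. `esmar` implements both model families,
the machinery needed to fit them correctly (lagged-predictor construction,
night breaks, missing-data rules, common-case model comparison), and a
Monte-Carlo harness quantifying how reliably information criteria recover
the true number of levels.

## The models

Let $y_{bdi}$ be the affect score of person $i$ at beep $b$ of day $d$
(affect is typically scored on a 1–100 slider scale).

**Two-level AR(1).** Ignoring the day structure ($y_{bi}$ indexed by
occasion within person):
$$y_{bi} = \mu_i + \phi_i (y_{b-1,i} - \mu_i) + e_{bi}, \qquad
  \mu_i = \gamma_{00} + u_{0i}, \quad \phi_i = \gamma_{10} + u_{1i},$$
with $e_{bi} \sim N(0, \sigma_e^2)$ and $(u_{0i}, u_{1i})$ jointly normal
(SDs $\sigma_{u0}, \sigma_{u1}$, correlation $r$). The lagged predictor is
centered on the person's *trait level* $\mu_i$ so that the intercept stays
interpretable as that trait level and a normal distribution is placed on
it rather than on the uncentered intercept $\mu_i(1-\phi_i)$.

**Three-level AR(1).** Day means get their own autoregression:
$$y_{bdi} = \mu_{di} + \zeta_i (y_{b-1,di} - \mu_{di}) + e_{bdi}, \qquad
  \mu_{di} = \mu_i + \beta_i (\mu_{d-1,i} - \mu_i) + r_{0di},$$
with day residual $r_{0di} \sim N(0, \sigma_r^2)$, beep-level inertia
$\zeta_i$ and day-level inertia $\beta_i$, both (with the trait level)
varying over persons. The beep-level predictor is now centered on the *day
mean* $\mu_{di}$, which is what allows day means to be modeled — and which
makes the two AR models non-nested, so a likelihood-ratio test cannot
compare them.

Empty (intercepts-only) two- and three-level models are the special cases
without the autoregressive terms; they serve to decompose variance and,
more importantly here, to supply the centering quantities.

## Building the lagged predictors

The centered lags are built in two stages, before the AR fits:

1. Fit the empty two-level model by ML; the empirical-Bayes (BLUP)
   residuals $e_{bi} = y - (\hat\gamma_{00} + \hat u_{0i})$ are the
   trait-centered scores. Their within-day lag-1 shift is `lev1pred`.
   EB estimates are used rather than person sample means because the
   shrinkage $\hat u_{0i} = \lambda_i(\bar y_i - \hat\gamma_{00})$,
   $\lambda_i = \sigma_{u0}^2 / (\sigma_{u0}^2 + \sigma_e^2 / n_i)$,
   gives slightly less biased inertia estimates; sample-mean centering
   remains available (`build_predictors(..., center = "sample")`) as a
   sensitivity option.
2. Fit the empty three-level model; its beep residuals (day-centered
   scores) lag to `lev1predfor3l`, and its BLUP day deviations
   $\hat r_{0di}$, broadcast over each day and shifted by one day within
   person, give `lev2pred`, the lagged centered day mean.

Two boundary rules matter. The *night break*: the first beep of a day is
never regressed on the previous evening's last beep — each day's series is
treated as a fresh stationary segment, so within-day lags stop at the day
boundary. And *whole-day gaps*: `lev2pred` is missing on each person's
first day and on any day whose entire previous day is unobserved; a day
with only some beeps missing still contributes a day deviation estimated
from its observed beeps. Missing outcomes propagate into the lags, and the
AR fits apply listwise deletion. The empty models, by contrast, are always
fitted to *all* observed cases, even when the AR models later use a
subset: centering should use all available information.

## Fitting

All models are Gaussian linear mixed models, estimated by maximum
likelihood (not REML — log-likelihoods must be comparable across models
with different fixed effects). The implementation profiles the fixed
effects and residual variance out of the marginal likelihood and optimizes
the remaining *relative* covariance parameters: the Cholesky factor of the
person-level covariance divided by $\sigma_e^2$ (diagonal when random
effects are uncorrelated) and the relative day-intercept SD. Each person's
marginal covariance is $\sigma_e^2 (I + Z_i \Lambda Z_i' + s^2 D_i D_i')$;
writing $U = [Z_i L, s D_i]$, determinant and inverse reduce to the small
matrix $I + U'U$, whose day block is diagonal, so one likelihood
evaluation costs a handful of $q \times q$ operations per person
($q \le 3$). The kernel is compiled (RcppArmadillo).

Numerical choices, all of them conventional for this model class:

* optimizer: derivative-free BOBYQA with lower bounds of 0 on the scale
  parameters (Cholesky diagonal, day SD), so variance estimates may land
  exactly on the zero boundary; boundary fits are flagged, kept, and enter
  model selection rather than being rejected;
* convergence: relative tolerance $10^{-8}$ on the profiled deviance;
  starting values 1 (relative intercept SD), 0.1 (relative slope SDs),
  0.4 (relative day SD), 0 (covariances); fits are deterministic — no
  random restarts;
* a residual sum of squares is floored at $10^{-12}$ so that degenerate
  (constant-outcome) data yield a clean boundary fit instead of an
  infinite likelihood;
* parameter counts $k$ follow the usual mixed-model AIC convention (fixed
  effects + variance/covariance components + residual variance), matching
  what `lme4` reports, so criteria are comparable across software;
* fixed-effect tests are Wald $z$ statistics; likelihood-ratio tests use
  the naive $\chi^2$ reference with degrees of freedom equal to the
  parameter-count difference. For variance components on the boundary this
  reference is conservative; this is documented rather than corrected.

One deliberate departure from the formula sometimes used for the
three-level AR model in `lmer` syntax, `(1 | Person/Day) +
(1 + lev2pred + lev1predfor3l | Person)`: that specification contains the
person intercept twice and hence splits one variance across two
parameters. `esmar`'s families always contain exactly one person-intercept
variance (the canonical identifiable form); with uncorrelated random
effects the two parameterizations induce the same marginal model, but the
canonical form is also what the parameter count assumes.

## Choosing the number of levels

The intuitive procedure — test the day-level variance in the empty
three-level model, or compare the empty models — is unreliable: beep-level
inertia alone produces "significant" day-level variance, because
consecutive beeps on the same day resemble each other and thereby mimic
day-mean fluctuation. The recommended procedure therefore compares *AR*
models only: the two-level AR(1) model and three three-level AR(1)
variants (no day inertia; fixed day inertia; fixed + random day inertia),
all with uncorrelated random effects so that the complexity gap between
families stays small. Because the day-lagged predictor costs extra cases,
all four models are refitted on the *common case subset* — the rows usable
by the most demanding model — which is what makes their AIC/BIC values
comparable. Three levels are chosen iff a three-level family attains the
lowest criterion; exact ties (never observed in practice) resolve to the
more parsimonious two-level side. Non-converged fits are dropped from the
comparison with a recorded warning rather than aborting the run.
`select_levels()` implements the procedure; `empirical_workflow()` wraps
it from a CSV file to a report.

## The simulators

`simulate_ar2()`, `simulate_ar3()` and `simulate_empty3()` generate
complete balanced panels from the three generating processes. Person
effects are drawn jointly multivariate normal; sampled inertias outside
the stationary region are truncated, $\ge 1 \mapsto 0.99$ and (by
symmetric extension, the negative case being vanishingly rare at realistic
parameters) $\le -1 \mapsto -0.99$. Day means follow a stationary AR(1)
across days; conditional on its day mean, each day's beep series is an
independent stationary AR(1) — the first beep of a day is drawn from the
within-day stationary distribution $N(\mu_{di}, \sigma_e^2/(1-\zeta_i^2))$
rather than started at the mean, which avoids first-beep variance
artifacts and makes the three-level process reduce *exactly* in
distribution to the two-level one when $\sigma_r = 0$, $\beta = 0$.
Whether the original simulations initialized this way is not documented
anywhere we know of; the effect of the choice is $O(1/N_b)$.

Randomness is disciplined: every person consumes a dedicated substream
derived deterministically from the root seed, so enlarging the panel never
reshuffles earlier persons, and every study replicate likewise has its own
substream, making results independent of evaluation order and replicate
count. The simulators emit complete data by default (the simulation study
is a complete-data design); an MCAR thinning rate is available for
missing-data plumbing. What the generator does *not* emulate: unequal and
irregular beep spacing within days, planned gaps, non-Gaussian or skewed
affect scales, floor/ceiling effects, time trends, weekday/weekend cycles,
and informative missingness. Passing tests therefore demonstrate
correctness of the method under its own assumptions, not robustness of the
substantive conclusions to these features of real ESM data.

Default parameter values are baked in as the study conditions:
`sim_params_2l()` ($\gamma_{00}=58$, $\gamma_{10}=0.37$, $\sigma_{u0}=12$,
$\sigma_{u1}=0.14$, $\sigma_e=15$, $r=-0.44$) and `sim_params_3l()`
($\gamma_{000}=58$, $\gamma_{010}=0.27$, $\gamma_{100}=0.16$,
$\sigma_{u00}=13$, $\sigma_{u01}=0.22$, $\sigma_{u10}=0.13$, $\sigma_r=7$,
$\sigma_e=15$, correlations $-0.45$, $-0.365$, $0.22$), resembling
multilevel AR estimates for positive affect in student ESM samples; the
five demonstration processes A–E are available via `artifact_params()`.

## Known biases of the two-stage procedure

The centered-lag construction is deliberately faithful to standard
practice, and it carries that practice's small-sample biases, which the
package's own simulations make visible:

* the trait-centered inertia of the two-level AR model has a negative bias
  of order $(1+3\phi)/(N_d N_b)$ — negligible at typical panel sizes;
* the *day*-centered beep inertia of the three-level AR model is biased by
  order $(1+3\zeta)/N_b$, because each day mean is estimated from the same
  $N_b$ beeps it centers: with 10 beeps/day a true $\zeta = 0.16$ is
  estimated near $0.06$ on average. This is the same mechanism that makes
  the three-level fit of genuinely two-level AR data deflate inertia;
* the day-level inertia is biased by order $(1+3\beta)/N_d$, and the
  lagged day-mean predictor is itself an EB estimate, so its coefficient
  is additionally attenuated and the day-level residual SD correspondingly
  inflated (roughly 10% at 21 days, 10 beeps/day).

For this reason the test suite checks strict Monte-Carlo recovery (truth
within three replicate SDs of the replicate mean) only for parameters the
two-stage estimator estimates without centering bias, and applies the
first-order bias allowances above to the inertia means and day SD. These
biases are a property of the estimator, not a defect of the
implementation: the level-*selection* procedure, which is the package's
point, is validated directly by its power and Type I error rates.

## Problem sizes and reproducibility

The demonstrations regenerate their processes at the published design of
90 persons × 21 days × 10 beeps/day and, being single stochastic
realizations in origin, are reported here as mean ± SD over 5 independent
panels. The selection study runs at a desk-scale default of 200 replicates
per cell (`reps = 1000` reproduces the full-scale design); the test suite
uses 40–100 replicates per cell with tolerances of three binomial SEs at
the replicate count actually used. `scripts/acceptance.R` re-derives the
headline quantities — the five artifact estimates and three study cells —
from scratch at 200 replicates per cell under a caller-supplied seed.

## Limitations

Beyond the generator limitations above: estimation is ML only (no REML,
by design); fixed-effect inference is Wald-based (no Satterthwaite or
Kenward–Roger degrees of freedom); lag order is fixed at 1; continuous-time
models for irregular spacing, trend and cyclic components, and
regime-switching dynamics are out of scope. The selection procedure's
operating characteristics were mapped under one empirically motivated
parameter regime; its headline sensitivity — power collapses when there
are fewer than about 9 beeps per day, and more days cannot compensate —
should be kept in mind when designing studies intended to resolve the
day-level question.
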