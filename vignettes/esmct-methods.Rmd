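---
title: "Continuous-time modeling of unequally spaced experience-sampling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time modeling of unequally spaced experience-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmct)
```

## The problem

Experience-sampling (ESM) studies prompt participants several times a day,
usually at a random moment inside consecutive time blocks
("signal-contingent sampling"), and continue over many days. The resulting
time series are *unequally spaced*: within-day intervals vary randomly
around one block, and every night inserts a gap several blocks long. Yet
the workhorse models in affect dynamics and related fields — the AR(1) and
VAR(1) models — assume that exactly one unit of time separates every pair
of consecutive observations. `esmct` implements both the discrete-time
models and their continuous-time counterpart, an exact simulator for the
latter under realistic beep schedules, and a simulation harness that
quantifies how much the equal-spacing assumption biases the estimated
dynamics.

## Models

The discrete-time VAR(1) model for a K-variate series is

$$ y_i = c + \Phi\, y_{i-1} + \epsilon_i, \qquad
   \epsilon_i \sim N(0, \Sigma_\epsilon), \qquad
   \Sigma_\epsilon = \Sigma_y - \Phi \Sigma_y \Phi' , $$

with stationarity requiring the spectral radius of $\Phi$ below one. Its
continuous-time analog (the CVAR(1), i.e. the multivariate
Ornstein–Uhlenbeck process) replaces the per-step regression with a drift
matrix $B$ whose eigenvalues have negative real part. Its exact solution
between any two observation times is

$$ y_{t_i} = e^{B\Delta_i} y_{t_{i-1}} + \epsilon_{\Delta_i}, \qquad
   \epsilon_{\Delta_i} \sim N\!\big(0,\;
   \Sigma_y - e^{B\Delta_i}\Sigma_y e^{B'\Delta_i}\big), $$

where $\Delta_i$ is the true elapsed interval. The implied regression
matrix at any lag is $\Phi(\Delta) = e^{B\Delta}$, which in the univariate
case is the lag-scaling rule $\phi(\Delta) = \phi(1)^\Delta$: a process
with a one-block autocorrelation of 0.1 has autocorrelation
$0.1^{0.5} \approx 0.32$ at half a block and $0.1^{1.5} \approx 0.03$ at a
block and a half. Because this decay is convex, intervals that are
symmetric around one block do *not* average out — short intervals carry
disproportionately high correlation, which is the root of the bias studied
here.

`phi_of_delta()`, `drift_of_phi()`, `innovation_cov_ct()`,
`innovation_cov_dt()`, `diffusion_of()` and `stationary_mean()` implement
these translations exactly (matrix exponential and principal matrix
logarithm). A $\Phi$ with an eigenvalue on the closed negative real axis
has no real continuous-time representation, and `drift_of_phi()` raises a
typed error rather than returning a complex drift.

## The schedule generator

`generate_schedule()` emulates the canonical simulation design: each day
holds `beeps_per_day` back-to-back blocks of `block_minutes` (defaults 10
and 90, a 15-h waking day), one uniform beep per block. Internal time is
measured in block units — $\Delta = 1$ is one block — and a calendar day
spans $24\cdot60/\texttt{block\_minutes}$ block units, so the unobserved
night appears as an overnight gap with expectation 7 blocks for the
default design. Under this design the within-day interval is the sum of
two independent uniforms, i.e. triangular on $[0, 2]$ blocks with mode 1
(`triangular_law()`, `triangular_stats()`): mean 90 min and variance
1,350 min² for 90-min blocks.

When a minimum interval is requested (`min_interval_blocks = 1/6` is the
15-min rule), the later beep of an offending pair is redrawn within its
block until the constraint holds. This rejection scheme preserves
per-block uniformity conditional on feasibility; the truncated interval
distribution then has a mean above the mode and a reduced variance. The
rule applies within days only — overnight gaps are always long. The
generator rejects configurations whose minimum interval reaches a full
block.

`generate_empirical_schedule()` mimics a week-long adolescent ESM design:
7 days, up to 8 prompts between 8 AM and 10 PM (one in 8–10 AM, six
100-min blocks in 10 AM–8 PM, one in 8–10 PM), with the block unit set to
105 min, the design's intended mean interval. Because participants answer
with a delay bounded by each block's response window (2 h morning, 1.5 h
daytime, 4 h evening) and sometimes not at all, recorded times are
*response* times: short realized intervals occur and roughly 50 of the 56
prompts are answered under the defaults. The real delay distribution is
unknown, so it is exposed as configuration (truncated exponential, mean
15 min by default, chosen so the realized mean interval stays near
105 min) rather than asserted as a finding.

## Exact simulation

`simulate_cvar()` draws the first observation from the stationary law
$N(0, \Sigma_y)$ and each subsequent one from the exact transition above,
using the *true* intervals including overnight gaps, so consecutive days
remain weakly correlated (by $\phi^7$ on average) exactly as a continuous
process implies. Because the transition is the closed-form solution of the
stochastic differential equation, there is no discretization error at any
interval length; the marginal law is $N(0, \Sigma_y)$ at every time point,
which the test suite verifies by moment checks. Innovation Cholesky
factors are cached per unique interval. Defaults standardize the process
(unit stationary variances, zero mean), matching how such simulation
studies are usually set up.

## The four interval-handling implementations

`interval_spec()` encodes how intervals enter the likelihood:

| Mode | Assumed interval | Interpretation |
|------|------------------|----------------|
| MI1  | always 1 | naive AR/VAR: even nights are one block |
| MI2  | 1 within days, 7 overnight | the common "mask the night" practice |
| MI3  | true interval rounded to the nearest 1/6 block | phantom-variable-style approximation |
| MI4  | exact interval | the true continuous-time model |

All four are fit by the *same* estimator (`fit_ct_ml()`), so differences
in results are attributable purely to the interval assignment. An MI3
interval that would round to zero is promoted to one precision unit,
because a zero interval makes the conditional density degenerate. A
rounding-rule subtlety: snapping the cumulative *times* to the 1/6 grid
and differencing is a distinct scheme that can shift individual intervals
by one grid step (while preserving sums); `esmct` rounds the *intervals*,
which is the behavior the MI3 definition states, and exposes the precision
as a parameter.

## Estimation

`fit_ct_ml()` maximizes the exact Gaussian likelihood: the stationary
density of the first observation (matching the generator's stationary
initial draw; a condition-on-first option exists) plus the Markov
transition densities with the assigned intervals. Because there is no
measurement noise in the model, this factorization is exact and no
filtering is needed. Numerical choices:

* **Stationarity by construction.** Univariate drift is parameterized as
  $B = -e^\theta$; the bivariate drift is optimized unconstrained with a
  barrier on eigenvalue real parts; $\Sigma_y$ uses a log-Cholesky
  parameterization. Every likelihood evaluation therefore sees valid
  interval-specific innovation covariances (invalid interior points are
  penalized, not silently clipped).
* **Optimizer protocol.** BFGS started from the least-squares $\Phi$
  mapped through the matrix logarithm (fallback $B = -I$), relative
  tolerance $10^{-12}$, up to five deterministically jittered restarts.
  Nonconvergence is flagged on the returned object, never thrown.
* **Speed.** For $K = 2$ the matrix exponentials for all intervals are
  evaluated in one vectorized pass through the eigendecomposition of $B$
  (with a per-interval `expm` fallback if $B$ is near-defective), so a
  10,000-observation likelihood evaluation is a handful of vector
  operations.
* **Boundary.** A univariate fit driving $\phi(1)$ below $10^{-8}$ is
  reported as an exact 0 with a degenerate interval, the natural reading
  of a white-noise boundary estimate.
* **Centering.** Data are mean-centered per person before fitting and the
  intercept is fixed at zero; `stationary_mean()` retains full intercept
  support for other uses.

`fit_ar_ols()` is the discrete-time baseline an applied researcher would
run with `lm()`: per-equation least squares with the lagged predictor set
to missing for each day's first observation. Its confidence intervals may
include negative values; the continuous-time model's cannot.

`phi_ci()` reports $\phi(\Delta) = e^{\hat B\Delta}$ with a delta-method
interval. In the univariate case the interval is computed on the
unconstrained $\theta$ scale and transformed monotonically, so bounds
always lie in $[0, 1)$. The delta method was chosen over profile
likelihood because it is standard, cheap, and directly testable: a
500-replicate coverage simulation at 50 observations per series is part of
the acceptance suite (observed coverage is near, and slightly above, the
nominal 95% — the conservatism comes from the curvature of the
transformation, and the reported standard error itself is calibrated to
the empirical sampling spread).

## The bias study

`run_condition()` / `summarize_bias()` / `run_full_study()` orchestrate
the simulation grid: nine univariate truths $\phi(1) = 0.1, \dots, 0.9$, a
bivariate truth with realistic affect-dynamics magnitudes, long series
(1,000 days) versus many short series (10 days), with and without the
15-min minimum interval. Reported measures are the absolute bias
(estimate − truth), the relative bias (divided by |truth|), and — for
replicated short series — the *median* (relative) estimation error, since
near the parameter bounds the error distribution is skewed and the mean
misleads. For a single long series the "bias" is a single-realization
estimation error and is labeled as such; `n_reps_long` can be raised to
separate the estimand bias from realization noise. Replicate seeds derive
deterministically from the condition seed (`derive_seed()`), so any cell
reruns in isolation, bitwise. Nonconverged fits are excluded with a count.

Key reproducible findings at these study conditions, all exercised by the
test suite: the within-day spacing variability inflates small
autocorrelations under MI1/MI2 (at $\phi(1) = 0.1$ the large-sample MI2
estimand is $\big((\phi - 1)/\ln\phi\big)^2 \approx 0.153$, a relative
bias above 50%, with single-realization values ranging to 70% and
beyond); MI1's additional night-as-one-block error turns the bias strongly
negative for $\phi \ge 0.5$; for 100-observation series the median error
of MI3/MI4 is negative at every truth; and MI3 is barely distinguishable
from the exact model. A caution for single-realization readings: with
10,000 observations the per-entry sampling spread of $\hat\Phi$ is about
0.01, so bivariate entries whose true (asymptotic) bias is smaller than
that — in particular the sign pattern of the nearly unbiased MI3/MI4 fits,
and MI1's smallest entries — are not stable across realizations. A
deterministic expected-likelihood calculation places the MI1 asymptotic
bias of $\phi_{11}$ slightly *below* zero for the bivariate truth used
here, so readings of single runs that show it positive reflect realization
noise.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen to keep Monte-Carlo error
well below each asserted effect: schedule-law checks pool $10^5$ gaps;
long-series conditions use 1,000 days with three (univariate) or six
(bivariate) averaged replicates; the short-series suite uses 500
replicates of 10-day series per truth (the Monte-Carlo SE of the median,
about 0.006, sits below the smallest asserted effect, −0.011); coverage
uses 500 replicates at 50 observations.

## What the generator does and does not emulate

The synthetic data are exactly stationary, Gaussian, noise-free
measurements of a first-order process with a time-invariant drift. Real
ESM data add measurement error, scale coarseness (1–7 Likert averages),
trends, skewness, ceilings, day-of-week structure, and nonresponse
correlated with state. Passing these checks therefore demonstrates
correctness of the estimators *under the model*, and quantifies the cost
of interval misspecification in isolation — it does not certify any model
as adequate for a given empirical series. The empirical-style schedule
reproduces the timing texture of a real design (response delays, short
intervals, about 50 completed observations) but not these substantive
artifacts.

## Known limitations

* The ML fitter supports $K \in \{1, 2\}$ (the dimensions studied);
  `cvar_loglik()` itself is general-K.
* No multilevel/random-effects or Bayesian estimation; single-person
  series only.
* No measurement-error (latent state) extension; with observation noise
  the Markov factorization used here would no longer be exact.
* Delta-method intervals are symmetric on the transformed scale and can be
  conservative near the zero boundary.
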