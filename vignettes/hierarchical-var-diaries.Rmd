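---
title: "Hierarchical Bayesian VAR models for multi-patient diary panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian VAR models for multi-patient diary panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bhvar)
```

## The problem

Daily diary studies follow a modest number of patients (tens) over a
modest number of days (tens to low hundreds), recording a few variables
per day — for instance daily tobacco use, negative affect and substance
craving in a college recovery community, or functional somatic symptoms
and psychological discomforts in primary-care patients. The scientific
questions are dynamic: does yesterday's craving predict today's tobacco
use, how strongly does each process feed back on itself, and how much do
these dynamics differ between patients?

A first-order vector autoregression answers such questions, but a
separate VAR per patient is fragile at these sample sizes: with $R$
variables and order $p$ each patient contributes $T_n - p$ observations
to estimate $R^2 p$ coefficients, so maximum-likelihood estimates have
large variance and can be singular outright for short diaries. `bhvar`
fits one joint hierarchical model instead, pooling information across the
panel while preserving patient-level estimates.

## The model

For patient $n = 1, \dots, N$ with observations
$y_{nt} \in \mathbb{R}^R$:

$$ y_{nt} = \sum_{i=1}^{p} A_{ni}\, y_{n,t-i} + \varepsilon_{nt}, \qquad
   \varepsilon_{nt} \sim \mathrm{MVN}(0, \Lambda^{-1}), $$

with a precision matrix $\Lambda$ shared across patients. Writing
$w_n = \mathrm{vec}([A_{n1}, \dots, A_{np}])$ (column-major within each
lag block; see `coef_to_matrices()`), the coefficients decompose as

$$ w_n = w + v_n, $$

a population-level vector $w$ plus patient deviations
$v_n \sim \mathrm{MVN}(0, \Theta_v^{-1})$ with diagonal $\Theta_v$.

The population vector carries a doubly adaptive elastic-net prior:
$w \sim \mathrm{MVN}(0, D^{-1})$ with
$D_{kk} = \lambda_{2,k} + 1/(2\tau_k^2)$, the latent scales
$2\tau_k^2 \sim \mathrm{Exp}(\lambda_{1,k}^2 / (2\xi_k^2))$, and Gamma
hyperpriors on the coefficient-specific L1 and L2 weights. Marginally
each $w_k$ mixes a Gaussian and a Laplace component, so posterior modes
are sparse while the fit remains smooth; $\xi_k^2$ is the conditional
variance of coordinate $k$ given the later coordinates under
$I_{Rp} \otimes \Lambda^{-1}$ (`compute_xi2()`), which ties the scale
prior to the innovation precision and keeps each coordinate's
conditional posterior unimodal. $\Lambda$ has a Wishart prior with scale
$K$ and degrees of freedom $\nu$, in the convention where the prior mean
is $\nu K$.

Gamma hyperpriors are parameterized by mean $m$ and degrees of freedom
$d$ (shape $d/2$, rate $d/(2m)$), so the defaults
$\lambda_{1,k}^2 \sim \Gamma(1, 0.001)$,
$\lambda_{2,k} \sim \Gamma(1, 0.01)$,
$\theta_{vk} \sim \Gamma(1, 0.01)$ are conjugate but nearly flat;
$\Lambda \sim \mathrm{Wishart}((R-1) I_R, 1)$ and the expansion factors
(below) are $\mathrm{MVN}(0, 100 I)$. `hyper_params()` exposes all of
them, a `shape_rate` switch for direct Gamma parameters, and an
`l1_prior_on` switch between placing the Gamma prior on
$\lambda_{1,k}^2$ (the default; the conditional is then exactly Gamma)
or on $\lambda_{1,k}$ itself (slice-sampled). The squared-weight reading
is the default because it is the one the near-flat default values are
stated for; the other reading is retained for sensitivity analysis.

## Posterior computation

`run_gibbs()` runs a Gibbs sampler with a multiplicative parameter
expansion: deviations enter the likelihood as $\alpha \circ v_n$ with an
auxiliary vector $\alpha$ given a diffuse normal prior. Without it, the
sampler alternates between small $v_n$ and large $\Theta_v$ in a
feedback loop and crawls; with it, the identified deviation
$v^*_n = \alpha \circ v_n$ mixes quickly. Neither $\alpha$, $v_n$ nor
$\theta_{vk}$ is identified alone — reported quantities are $w$,
$v^*_n$, $w_n = w + v^*_n$, $\Lambda$, and the heterogeneity SD
$|\alpha_k| / \sqrt{\theta_{vk}}$.

One sweep updates, in order: $w$ (conjugate MVN), each $v_n$ (conjugate
MVN), $\alpha$ (conjugate MVN), $\Lambda$, the latent scales
$2\tau^2_k$, the L1 weights, the L2 weights and $\theta_{vk}$
(conjugate Gamma). Three updates deserve comment:

* **$\Lambda$.** Its conditional is conjugate Wishart *times* the factor
  contributed by the $\xi^2$-dependent exponential prior on the latent
  scales. We draw from the conjugate Wishart (degrees of freedom
  incremented by $\sum_n (T_n - p)$) as an independence-Metropolis
  proposal and accept on the $\xi^2$ factor; acceptance rates in
  practice are around 0.85–0.95, and in the scalar case the exact
  closed form (a Gamma) is used as a test oracle.
* **$2\tau^2_k$ and $\lambda_{2,k}$.** Their conditionals are not named
  distributions (the $(\lambda_2 + 1/u)^{1/2}$ normalizer couples
  them), so both are slice-sampled on the log scale. Every conditional
  sampler — conjugate or not — is validated in the test suite against a
  closed form or a normalized 1-D numeric integration via two-sample
  Kolmogorov–Smirnov statistics at the 0.1% critical value, and the
  whole sampler is checked against a brute-force grid posterior on a
  scalar model.
* **Numerical guards.** Conditional precision matrices are symmetrized
  and, on a Cholesky failure, jittered by $10^{-10} I$ (counted per
  chain); positive scalar blocks are clamped to $[10^{-12}, 10^{12}]$ so
  that reciprocals and rate products stay finite under the near-flat
  hyperpriors; initial values for positive blocks are prior draws
  truncated to $[10^{-4}, 10^{4}]$.

Chains are seeded independently from a master seed and stored after
warmup with thinning; `(iterations - warmup) / thin` draws are kept per
chain. A commonly used heavy configuration is 4 chains of 10,000
iterations with the first half discarded and thinning by 20 (250 stored
draws per chain under this arithmetic; descriptions that quote 500 per
chain correspond to thinning a denser retained set). The suite and the
bundled acceptance script use 4 × 2,000 with thinning by 4, which on
panels of 25 patients × 26 days reproduces forecast metrics well within
their Monte-Carlo variability.

### Convergence monitoring

`gelman_rubin()` implements the classic between/within-chain potential
scale reduction factor. Applied to a fitted object it monitors the
*identified* parameters: $w$, $v^*_n$, $\Lambda$ and
$\log(|\alpha_k|/\sqrt{\theta_{vk}})$. The latent elastic-net scales and
per-coefficient penalty weights are deliberately excluded: at
coordinates the data does not inform, their joint conditional is a
multiplicative random walk over a nearly improper prior, so a
variance-based statistic on them never stabilizes and does not reflect
convergence of anything the model reports. They remain accessible via
`chain_matrices()` for manual inspection. On synthetic recovery panels
the monitored maximum is typically below 1.03.

## Preprocessing

`preprocess()` applies, per patient and variable: imputation →
log transform → standardization → linear detrending. Two imputation
rules are provided: `flank_mean` (each missing run filled with the mean
of its two flanking observed values; boundary runs copy the single
nearest value — the rule degenerates there because only one flank
exists) and `moving_average` (centered window mean, window widened at
the boundaries; default basis window 4). Gaps in the day index become
missing rows first, so lags always span calendar days. The log offset
defaults to 0 and should be 1 for count-like scales that include 0
(e.g. cigarettes); the log step can be disabled entirely for data
already on a continuous scale, such as the synthetic panels. The
standardize-then-detrend order matches the listed order of the source
protocol; since the two steps do not commute exactly, the applied order
is recorded in the panel's provenance attribute and can be flipped by
configuration. Standardization uses the sample SD (denominator
$T - 1$); constant series are an error rather than silently dropped.

Note one deliberate caveat: train/test splitting (`holdout_split()`)
happens *after* preprocessing, mirroring the study protocol. The
held-out day therefore participates in the per-patient standardization
and detrending — a mild form of leakage that is accepted for
comparability.

## Forecasting and evaluation

`posterior_forecast()` draws, for every stored posterior draw, a
recursive path: lag matrices from $w + v^*_n$, one innovation per step
from $\mathrm{MVN}(0, \hat\Lambda^{-1})$ with that draw's precision,
forecasts fed back as lags for horizons $h = 2, \dots, H$. Points are
predictive means (the MSE-optimal choice, even though parameter reports
use sparse modes) and intervals are the 2.5th/97.5th predictive
percentiles. `evaluate_forecasts()` computes per-variable MSE over
(patient, horizon) cells, overall MSE as the mean of per-variable MSEs,
95% interval coverage, and — given a comparator — the fraction of
strictly narrower intervals.

Baselines: `fit_var_mle()` (per-patient least squares, no intercept,
Gaussian plug-in forecast intervals from companion-power error
covariances, ignoring parameter uncertainty — the interval construction
is our choice, labelled as such) and `fit_enet_patient()` /
`enet_forecast_bootstrap()` (glmnet with mixing weight 0.5, 3-fold CV
with the one-standard-error rule, residual-bootstrap percentile
intervals, B = 500 by default). The elastic-net objective convention is
pinned by an independent coordinate-descent oracle in the test suite;
note that glmnet's internal response standardization makes the ridge
half of the penalty scale with $1/\mathrm{sd}(y)$.

## Point estimates and summaries

Parameter point estimates are empirical posterior modes: the stored draw
value maximizing a Gaussian KDE (Silverman bandwidth) evaluated at the
draws, ties broken toward the smallest absolute value. Restricting the
argmax to realized draws is cheap, and under the elastic-net prior it
yields exactly-zero modes when shrinkage concentrates draws at zero —
the sparsity that motivates mode-based reporting. Significance flags
mark equal-tailed intervals (type-7 quantiles, so interval tests are
exact) excluding zero at levels 0.10 and 0.05; flags are nested across
levels by construction. `heterogeneity_sd()` transforms draws to the SD
scale *before* taking modes, because modes do not commute with
nonlinear transforms. `summarize_by_group()` produces five-number
summaries of per-patient coefficient modes within demographic groups;
group summaries use the combined coefficients $w + v^*_n$ (the
patient's realized dynamics) while $v^*_n$ itself can be exported
separately.

`hier_aic()` supplies the order-selection criterion: the VAR log
likelihood at posterior-mode patient coefficients and posterior-mode
$\Lambda$, with $R^2p(N + 1) + R(R+1)/2 + 5R^2p$ parameters (population
and patient coefficient vectors, the free entries of $\Lambda$, and the
five per-coefficient hyperparameter vectors). The formula for the
parameter count of a hierarchical fit is a convention, recorded here so
alternatives can be compared; `select_order()` prefers the smaller AIC.

## The synthetic-data generator

`sample_truth()` / `simulate_panel()` instantiate the generative model:
a sparse population vector (zero with probability `sparsity`, nonzeros
uniform on $\pm[0.1, 0.6]$), deviations
$v_n \sim \mathrm{MVN}(0, \mathrm{diag}(\texttt{hetero\_sd}^2))$ with a
stationarity guard (companion spectral radius < 1, patients redrawn up
to 100 times), innovations from $\Lambda_{\mathrm{true}}$, optional
linear trends, and completely-at-random missingness. Series start from
zero lags and discard a 200-step burn-in rather than sampling the
stationary law directly — simpler, and indistinguishable after burn-in.

`simulate_study_panel()` fixes the study conditions used by the test
suite and the acceptance script: $N = 25$ patients, $R = 3$ variables,
$p = 1$, series lengths drawn from a normal with mean 25.5 and SD 5
clamped to $[10, 33]$ days, sparsity 0.5, heterogeneity SD 0.2,
identity innovation precision and 3% missing cells — the shape of a
25-patient daily diary study with an average of ~25.5 days and under one
missing day per patient. These values were fixed once, from the study
description, before any test outcome was observed.

What the generator does *not* emulate: ordinal 1–5 and bounded 1–150
response scales (the model operates post-transformation), informative
missingness, weekday structure, and measurement error distinct from
innovation noise. Passing recovery tests therefore demonstrate
correctness of the inferential machinery under the model's own
assumptions, not robustness to the ways real diaries violate them.

Two recovery notes. First, recovery suites fit the simulated panels on
their native scale: standardizing each series would rescale the true
coefficients by ratios of per-variable stationary SDs and invalidate
the comparison to the generating values. Second, even with long series
the population estimate has an error floor of order
$\mathrm{hetero\_sd}/\sqrt{N}$, because the panel identifies $w$ only up
to the sample mean of the realized patient deviations.

## Numerical and design choices

* `vec` convention: column-major within each lag matrix, lag blocks
  concatenated; all modules route through `coef_to_matrices()`.
* Update order in the sweep is fixed as listed; order invariance is not
  assumed.
* Equal-tailed intervals use type-7 quantiles throughout.
* The Wishart convention (prior mean $\nu K$) is pinned by a prior-only
  moment test, not assumed.
* Forecast draws use one fresh innovation per horizon step with
  $\hat\Lambda$ fixed within a draw.
* Degenerate inputs error early with the offending patient/variable
  named: all-missing series, zero-variance series, non-positive values
  before the log, duplicated (patient, day) rows without daily
  averaging, too-short series for a requested order.

## Known limitations

A single shared $\Lambda$ across patients (per the model); no
within-sampler handling of missing data (imputation precedes fitting);
no proper scoring rules beyond MSE/coverage/width; the AIC parameter
count for a hierarchical model is a convention, not a derivation; and
the empirical-mode estimator is deliberately crude — with few stored
draws its variance is visible, so mode-based reports should use a few
hundred draws or more.
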