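# bhvar — Bayesian hierarchical VAR models for multi-patient diary data

`bhvar` models multi-patient daily diary panels — a few variables per day
(e.g. tobacco use, negative affect, substance craving) for each of a few
dozen patients over a few weeks — with a single hierarchical vector
autoregression instead of one fragile VAR per patient. It is aimed at
biostatisticians and quantitative clinicians doing patient-level
predictive modelling on intensive longitudinal data.

## The model

For patient *n* with R-variate daily observations *y<sub>nt</sub>*:

    y_nt = Σ_{i=1..p} A_ni · y_{n,t−i} + ε_nt,   ε_nt ~ MVN(0, Λ⁻¹)

with the vectorized coefficients decomposed as

    w_n = w + v_n,     v_n ~ MVN(0, Θ_v⁻¹)

— a population-level vector *w* shared across patients plus
patient-level deviations. *w* carries a doubly adaptive elastic-net
prior: `w ~ MVN(0, D⁻¹)` with `D_kk = λ₂k + 1/(2τ²k)`,
`2τ²k ~ Exp(λ₁k²/(2ξ²k))`, and coefficient-specific Gamma-distributed L1
and L2 weights, conditioned on the innovation precision Λ (Wishart
prior) through the conditional variances ξ²k. Posterior modes are
sparse, so the fitted network of lag-1 associations is directly
interpretable; the diagonal of Θ_v quantifies between-patient
heterogeneity per coefficient.

Inference is a Gibbs sampler with multiplicative parameter expansion
(`v*_n = α ∘ v_n`), which breaks the deviation/precision feedback that
otherwise stalls hierarchical samplers. Conjugate conditionals are
sampled exactly; the innovation precision uses an
independence-Metropolis step with its conjugate Wishart as proposal; the
two non-named scalar conditionals are slice-sampled. Every conditional
is validated in the test suite against closed forms or numeric
integration (Kolmogorov–Smirnov at the 0.1% critical value), and the
whole posterior against a brute-force grid oracle on a scalar model.

The package also provides the diary preprocessing pipeline (daily
averaging, flank-mean or moving-average imputation, log transform,
standardization, detrending), posterior-predictive recursive
forecasting with MSE / 95%-coverage / interval-width evaluation, two
per-patient comparators (maximum-likelihood VAR; cross-validated
elastic net with one-SE rule and residual-bootstrap intervals), and a
synthetic-panel generator for the full generative model.

## Worked example

```r
library(bhvar)

sim   <- simulate_study_panel(seed = 42)          # 25 patients x 3 variables
panel <- preprocess(sim$panel, preprocess_config(log_transform = FALSE))

fit <- run_gibbs(panel, p = 1, chains = 2, iterations = 2000,
                 warmup = 1000, thin = 4, seed = 7)
fit
#> bhvar_draws: 2 chain(s) x 250 stored draws (2000 iterations, warmup 1000, thin 4)
#>   model: R = 3, p = 1, N = 25 patients, K = 9 coefficients
#>   Lambda MH acceptance rate: 0.92

head(coef_summary(fit, "w")[, c("coef", "mode", "lo05", "hi05", "sig05")], 4)
#>               coef         mode        lo05         hi05 sig05
#> 1 tobacco->tobacco  0.350473851  0.24398326  0.473127760  TRUE
#> 2  tobacco->negaff -0.140195151 -0.27611261 -0.001544541  TRUE
#> 3 tobacco->craving -0.002725237 -0.10990220  0.072014737 FALSE
#> 4  negaff->tobacco  0.233256834  0.08376819  0.342538149  TRUE

max(gelman_rubin(fit))
#> [1] 1.016246
```

Each `coef_summary` row is one lag-1 association ("X->Y" = yesterday's X
on today's Y): the sparse posterior mode, the 95% equal-tailed interval
and whether it excludes zero. Here the tobacco autocorrelation (mode
0.35) is the strongest population-level association, and the zero mode
for tobacco->craving shows the elastic-net shrinkage at work.
`heterogeneity_sd(fit)` returns the posterior-mode SD of the
patient-level deviations per coefficient, and
`posterior_forecast(fit, panel, H = 1)` gives per-patient
posterior-predictive means with 95% intervals.

`compare_models()` runs the hierarchical model against both per-patient
baselines under a shared last-day holdout:

```r
cmp <- compare_models(panel, p = 1, n_test = 1, chains = 2,
                      iterations = 2000, warmup = 1000, thin = 4, seed = 7)
print(cmp$table, digits = 3)
#>          model mse_overall coverage narrower_than_mle mse_tobacco mse_negaff mse_craving
#> 1 hierarchical       0.679    0.947            0.2800        1.11      0.512       0.415
#> 2  patient_mle       0.682    0.920                NA        1.18      0.456       0.412
#> 3  elastic_net       0.972    0.880            0.0667        1.49      0.769       0.654
```

A command-line front end over the same functions is installed at
`inst/cli/bhvar-cli.R` with subcommands
`simulate | preprocess | fit | summarize | forecast | evaluate | compare`
driven by a YAML config.

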