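#' Compare the hierarchical model with the per-patient baselines
#'
#' Runs the three forecasters — hierarchical Bayesian VAR, per-patient MLE
#' VAR and per-patient cross-validated elastic net — under a shared
#' train/test split and reports MSE (overall and by variable), 95%
#' interval coverage, and the fraction of Bayesian intervals narrower than
#' the MLE's.
#'
#' @param panel a preprocessed [diary_panel].
#' @param p VAR order (default 1).
#' @param n_test held-out days per patient (default 1).
#' @param chains,iterations,warmup,thin,hyper passed to [run_gibbs()].
#' @param seed master seed (sampler, CV folds, bootstrap, predictive
#'   noise).
#' @param enet_B bootstrap replicates for the elastic-net intervals.
#' @return A list with `fit` (the `bhvar_draws`), `split`, per-model
#'   forecast frames, per-model evaluation lists (`hier`, `mle`, `enet`)
#'   and a `table` data.frame shaped like a model-comparison report.
#' @export
compare_models <- function(panel, p = 1L, n_test = 1L, chains = 4L,
                           iterations = 2000L, warmup = iterations %/% 2L,
                           thin = 1L, hyper = NULL, seed = 1L,
                           enet_B = 500L) {
  split <- holdout_split(panel, n_test)
  fit <- run_gibbs(split$train, p = p, hyper = hyper, chains = chains,
                   iterations = iterations, warmup = warmup, thin = thin,
                   seed = seed)
  fc_hier <- posterior_forecast(fit, split$train, H = n_test,
                                seed = seed + 11L)
  fc_mle <- baseline_forecast_panel(split$train, H = n_test, method = "mle",
                                    p = p)
  fc_enet <- baseline_forecast_panel(split$train, H = n_test,
                                     method = "enet", p = p,
                                     seed = seed + 29L, B = enet_B)
  ev_hier <- evaluate_forecasts(fc_hier, split$test, comparator = fc_mle)
  ev_mle <- evaluate_forecasts(fc_mle, split$test)
  ev_enet <- evaluate_forecasts(fc_enet, split$test, comparator = fc_mle)
  tab <- data.frame(
    model = c("hierarchical", "patient_mle", "elastic_net"),
    mse_overall = c(ev_hier$mse_overall, ev_mle$mse_overall,
                    ev_enet$mse_overall),
    coverage = c(ev_hier$coverage, ev_mle$coverage, ev_enet$coverage),
    narrower_than_mle = c(ev_hier$width_narrower, NA, ev_enet$width_narrower),
    stringsAsFactors = FALSE)
  byv <- rbind(ev_hier$mse_by_variable, ev_mle$mse_by_variable,
               ev_enet$mse_by_variable)
  colnames(byv) <- paste0("mse_", panel$variable_names)
  tab <- cbind(tab, byv)
  rownames(tab) <- NULL
  list(fit = fit, split = split, forecasts = list(hier = fc_hier,
                                                  mle = fc_mle,
                                                  enet = fc_enet),
       hier = ev_hier, mle = ev_mle, enet = ev_enet, table = tab)
}
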