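#' Read a YAML analysis configuration
#'
#' Configuration files carry three optional blocks: `schema` (column-name
#' mapping for [read_panel_csv()]), `preprocess` (fields of
#' [preprocess_config()]) and `fit` (`p`, `chains`, `iterations`,
#' `warmup`, `thin`, `seed`, `n_test`, plus a `hyper` sub-block with
#' fields of [hyper_params()]). Unknown keys raise an error with the
#' offending field path.
#'
#' @param path YAML file path.
#' @return A named list with validated `schema`, `preprocess`, `fit`
#'   entries (missing blocks become defaults at the point of use).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config root must be a mapping")
  allowed <- list(
    schema = c("patient_id", "day", "variables", "demographics"),
    preprocess = c("imputation", "ma_window", "log_transform", "log_offset",
                   "standardize", "detrend", "standardize_before_detrend",
                   "daily_average"),
    fit = c("p", "chains", "iterations", "warmup", "thin", "seed", "n_test",
            "hyper"),
    hyper = c("mu1", "nu1", "mu2", "nu2", "k_theta", "s_theta",
              "wishart_dof", "alpha_prior_var", "gamma_param", "l1_prior_on"))
  bad_top <- setdiff(names(cfg), names(allowed))
  if (length(bad_top)) stop("unknown config field(s): ",
                            paste(bad_top, collapse = ", "))
  for (blk in intersect(names(cfg), c("schema", "preprocess", "fit"))) {
    bad <- setdiff(names(cfg[[blk]]), allowed[[blk]])
    if (length(bad)) stop("unknown config field(s): ",
                          paste(paste0(blk, ".", bad), collapse = ", "))
  }
  if (!is.null(cfg$fit$hyper)) {
    bad <- setdiff(names(cfg$fit$hyper), allowed$hyper)
    if (length(bad)) stop("unknown config field(s): ",
                          paste(paste0("fit.hyper.", bad), collapse = ", "))
  }
  cfg
}

#' Build a [preprocess_config()] from a config block
#' @param block the `preprocess` list from [read_config()] (may be NULL).
#' @return A `preprocess_config`.
#' @export
preprocess_config_from <- function(block) {
  if (is.null(block)) return(preprocess_config())
  do.call(preprocess_config, block)
}
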