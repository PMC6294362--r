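#' Persist posterior draws as a columnar CSV store
#'
#' Writes one CSV per stored field (rows = draws across chains, with
#' `chain` and `draw` index columns) plus a YAML manifest recording the
#' sampler configuration, hyperparameters and the MD5 checksum of every
#' file, so a fit can be re-loaded or re-verified later.
#'
#' @param draws a `bhvar_draws` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(draws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- draws$config
  fields <- c("w", "alpha", "v", "v_star", "w_n", "Lambda", "two_tau2",
              "lam1sq", "lam2", "theta_v")
  files <- character(0)
  for (f in fields) {
    per_chain <- lapply(seq_along(draws$chains), function(i) {
      x <- draws$chains[[i]][[f]]
      m <- if (length(dim(x)) == 2) x else matrix(x, nrow = dim(x)[1])
      data.frame(chain = i, draw = seq_len(nrow(m)), m)
    })
    df <- do.call(rbind, per_chain)
    path <- file.path(dir, paste0(f, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <- c(files, path)
  }
  manifest <- list(
    package = "bhvar",
    config = cfg[c("R", "p", "K", "N", "chains", "iterations", "warmup",
                   "thin", "n_keep", "seed")],
    chain_seeds = as.integer(draws$config$chain_seeds),
    patient_ids = cfg$patient_ids,
    variable_names = cfg$variable_names,
    hyper = list(mu1 = draws$hyper$mu1, nu1 = draws$hyper$nu1,
                 mu2 = draws$hyper$mu2, nu2 = draws$hyper$nu2,
                 k_theta = draws$hyper$k_theta,
                 s_theta = draws$hyper$s_theta,
                 wishart_dof = draws$hyper$wishart_dof,
                 alpha_prior_var = draws$hyper$alpha_prior_var,
                 gamma_param = draws$hyper$gamma_param,
                 l1_prior_on = draws$hyper$l1_prior_on),
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Load a persisted draw store
#'
#' Reads the manifest and field CSVs written by [write_draws()], verifying
#' checksums, and reconstructs a `bhvar_draws` object.
#'
#' @param dir directory written by [write_draws()].
#' @return A `bhvar_draws` object (without the original `hyper` matrices).
#' @export
read_draws <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  for (fn in names(manifest$checksums)) {
    path <- file.path(dir, fn)
    if (!file.exists(path)) stop("draw store file missing: ", fn)
    if (unname(tools::md5sum(path)) != manifest$checksums[[fn]]) {
      stop("checksum mismatch for ", fn)
    }
  }
  cfg <- manifest$config
  R <- cfg$R
  K <- cfg$K
  N <- cfg$N
  fields <- c("w", "alpha", "v", "v_star", "w_n", "Lambda", "two_tau2",
              "lam1sq", "lam2", "theta_v")
  chains <- vector("list", cfg$chains)
  for (f in fields) {
    df <- utils::read.csv(file.path(dir, paste0(f, ".csv")))
    for (i in seq_len(cfg$chains)) {
      m <- as.matrix(df[df$chain == i, -(1:2), drop = FALSE])
      dimnames(m) <- NULL
      if (f %in% c("v", "v_star", "w_n")) {
        m <- array(m, c(nrow(m), N, K))
      } else if (f == "Lambda") {
        m <- array(m, c(nrow(m), R, R))
      }
      chains[[i]][[f]] <- m
    }
  }
  structure(list(chains = chains,
                 config = list(R = R, p = cfg$p, K = K, N = N,
                               chains = cfg$chains,
                               iterations = cfg$iterations,
                               warmup = cfg$warmup, thin = cfg$thin,
                               n_keep = cfg$n_keep, seed = cfg$seed,
                               chain_seeds = manifest$chain_seeds,
                               patient_ids = manifest$patient_ids,
                               variable_names = manifest$variable_names,
                               coef_names =
                                 coef_labels(manifest$variable_names, cfg$p)),
                 hyper = manifest$hyper),
            class = "bhvar_draws")
}
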