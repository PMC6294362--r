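#' Empirical posterior mode of a draw vector
#'
#' Returns the draw value maximizing a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth) evaluated at the draw points; the
#' search is restricted to observed draws, so shrinkage draws at exactly 0
#' can be returned exactly. Ties (density within `1e-12` of the maximum)
#' are broken toward the smallest absolute value, favouring sparsity.
#'
#' @param draws numeric vector of at least 50 posterior draws.
#' @return The modal draw value (a scalar).
#' @export
empirical_mode <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 50) stop("need at least 50 draws for a mode estimate")
  if (diff(range(draws)) == 0) return(draws[1])
  bw <- stats::bw.nrd0(draws)
  dens <- stats::density(draws, bw = bw, n = 1024,
                         from = min(draws) - bw, to = max(draws) + bw)
  f <- stats::approx(dens$x, dens$y, xout = draws)$y
  top <- which(f >= max(f) - 1e-12)
  draws[top[which.min(abs(draws[top]))]]
}

#' Equal-tailed credible interval
#'
#' Empirical quantiles at `(1 - level) / 2` and `1 - (1 - level) / 2`,
#' using linear-interpolation (type-7) quantiles.
#'
#' @param draws numeric vector of posterior draws.
#' @param level interval mass in (0, 1).
#' @return Numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), type = 7, names = FALSE))
}

#' Summarize coefficients: modes, intervals and significance flags
#'
#' For each coefficient of `field` ("w" for population coefficients or
#' "w_n" for per-patient coefficients), returns the empirical mode, an
#' equal-tailed interval at each requested level and a significance flag
#' (interval excludes 0).
#'
#' @param draws a `bhvar_draws` object.
#' @param field `"w"`, `"w_n"` or `"v_star"`.
#' @param levels significance levels (default `c(0.10, 0.05)`; the interval
#'   for level `a` has mass `1 - a`).
#' @return A data.frame with columns `coef` (and `patient_id` for
#'   patient-level fields), `mode`, and `lo`/`hi`/`sig` per level.
#' @export
coef_summary <- function(draws, field = c("w", "w_n", "v_star"),
                         levels = c(0.10, 0.05)) {
  field <- match.arg(field)
  cfg <- draws$config
  x <- pool_draws(draws, field)
  one <- function(colv, label, pid = NA_character_) {
    row <- list(coef = label, patient_id = pid, mode = empirical_mode(colv))
    for (a in levels) {
      ci <- credible_interval(colv, 1 - a)
      tag <- sprintf("%02.0f", 100 * a)
      row[[paste0("lo", tag)]] <- ci[1]
      row[[paste0("hi", tag)]] <- ci[2]
      row[[paste0("sig", tag)]] <- ci[1] > 0 || ci[2] < 0
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (field == "w") {
    out <- do.call(rbind, lapply(seq_len(cfg$K), function(k) {
      one(x[, k], cfg$coef_names[k])
    }))
  } else {
    out <- do.call(rbind, unlist(lapply(seq_len(cfg$N), function(n) {
      lapply(seq_len(cfg$K), function(k) {
        one(x[, n, k], cfg$coef_names[k], cfg$patient_ids[n])
      })
    }), recursive = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Posterior modes of the between-patient heterogeneity SDs
#'
#' Transforms each draw of the deviation precision to the implied standard
#' deviation of the patient-level coefficients and takes the empirical mode
#' of the transformed draws (the mode is not equivariant under nonlinear
#' transforms, so the transform comes first). For a fitted `bhvar_draws`
#' object the identified scale under the parameter expansion is used:
#' `v_star[k] ~ N(0, alpha_k^2 / theta_vk)` given the expansion factor, so
#' the SD draw is `|alpha_k| * theta_vk^(-1/2)`; for a plain matrix of
#' (unexpanded) precision draws it is `theta_vk^(-1/2)`.
#'
#' @param theta_draws draws of the deviation precisions: a matrix
#'   (draws x K), or a `bhvar_draws` object (fields `theta_v` and `alpha`).
#' @return Named numeric vector of per-coefficient SD modes (> 0).
#' @export
heterogeneity_sd <- function(theta_draws) {
  if (inherits(theta_draws, "bhvar_draws")) {
    nm <- theta_draws$config$coef_names
    sd_draws <- hetero_sd_draws(theta_draws)
    out <- apply(sd_draws, 2, empirical_mode)
    names(out) <- nm
    return(out)
  }
  theta_draws <- as.matrix(theta_draws)
  if (any(theta_draws <= 0)) stop("deviation precision draws must be positive")
  apply(theta_draws^(-0.5), 2, empirical_mode)
}

# Identified heterogeneity-SD draws |alpha| / sqrt(theta_v), pooled.
hetero_sd_draws <- function(draws) {
  th <- pool_draws(draws, "theta_v")
  if (any(th <= 0)) stop("deviation precision draws must be positive")
  abs(pool_draws(draws, "alpha")) / sqrt(th)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) formulation from between- and within-chain
#' variances: with `m` chains of length `n`, `B/n` the variance of chain
#' means and `W` the mean within-chain variance, returns
#' `sqrt(((n-1)/n * W + B/n) / W)` per parameter.
#'
#' @param chains list of per-chain draw vectors or matrices
#'   (draws x parameters), all the same length (>= 10); or a
#'   `bhvar_draws` object, in which case the statistic is computed over
#'   the model's identified parameters: `w`, `v_star`, `Lambda` and the
#'   heterogeneity SD `|alpha|/sqrt(theta_v)` (on the log scale). The raw
#'   `alpha`, `v` and `theta_v` are not identified under the parameter
#'   expansion, and the latent elastic-net scales and per-coefficient
#'   penalty weights have near-improper marginals at coordinates the data
#'   does not inform, so variance-based R-hat is undefined there; pass
#'   [chain_matrices()] output explicitly to diagnose those blocks.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "bhvar_draws")) {
    fields <- c("w", "v_star", "Lambda", "hetero_sd")
    get_chain <- function(f, i) {
      if (f == "hetero_sd") {
        ch <- chains$chains[[i]]
        log(abs(ch$alpha) / sqrt(ch$theta_v))
      } else {
        chain_matrices(chains, f)[[i]]
      }
    }
    per_chain <- lapply(seq_along(chains$chains), function(i) {
      do.call(cbind, lapply(fields, get_chain, i = i))
    })
    names_all <- unlist(lapply(fields, function(f) {
      nc <- if (f == "hetero_sd") ncol(chains$chains[[1]]$theta_v)
            else ncol(chain_matrices(chains, f)[[1]])
      paste0(f, "[", seq_len(nc), "]")
    }))
    rh <- gelman_rubin(per_chain)
    names(rh) <- names_all
    return(rh)
  }
  stopifnot(is.list(chains), length(chains) >= 2)
  mats <- lapply(chains, function(x) if (is.matrix(x)) x else cbind(x))
  n <- nrow(mats[[1]])
  stopifnot(n >= 10, all(vapply(mats, nrow, 0L) == n))
  P <- ncol(mats[[1]])
  vapply(seq_len(P), function(j) {
    cols <- vapply(mats, function(m) m[, j], numeric(n))
    means <- colMeans(cols)
    W <- mean(apply(cols, 2, stats::var))
    B_over_n <- stats::var(means)
    if (W < .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
}

#' Sample autocorrelation of a chain
#'
#' @param chain numeric vector of draws.
#' @param max_lag largest lag (must be below the chain length).
#' @return Numeric vector of autocorrelations at lags `0..max_lag`
#'   (`acf(0) = 1`).
#' @export
chain_autocorrelation <- function(chain, max_lag = 20L) {
  stopifnot(length(chain) > max_lag)
  drop(stats::acf(chain, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
}

#' Five-number summaries of patient coefficient modes by group
#'
#' Splits patients into labelled groups and summarizes, per group and per
#' coefficient, the distribution of the per-patient posterior modes
#' (minimum, lower quartile, median, upper quartile, maximum).
#'
#' @param patient_modes numeric matrix (patients x K) of per-patient
#'   coefficient modes, e.g. modes of the combined coefficients `w + v_star`
#'   from [coef_summary()].
#' @param labels group label per patient (length = rows of
#'   `patient_modes`); every patient must be labelled and no group empty.
#' @param coef_names optional coefficient labels.
#' @return A data.frame with columns `group`, `coef`, `min`, `q1`,
#'   `median`, `q3`, `max`, `n`.
#' @export
summarize_by_group <- function(patient_modes, labels, coef_names = NULL) {
  patient_modes <- as.matrix(patient_modes)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(patient_modes))
  if (anyNA(labels)) stop("every patient must be labelled")
  if (is.null(coef_names)) {
    coef_names <- colnames(patient_modes)
    if (is.null(coef_names)) coef_names <- paste0("w", seq_len(ncol(patient_modes)))
  }
  groups <- split(seq_along(labels), labels)
  if (any(lengths(groups) == 0)) stop("empty group")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    do.call(rbind, lapply(seq_len(ncol(patient_modes)), function(k) {
      v <- patient_modes[idx, k]
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                           names = FALSE)
      data.frame(group = g, coef = coef_names[k], min = q[1], q1 = q[2],
                 median = q[3], q3 = q[4], max = q[5], n = length(idx),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
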