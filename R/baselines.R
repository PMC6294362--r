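#' Per-patient maximum-likelihood VAR fit
#'
#' Equation-by-equation least squares on the lagged design with no
#' intercept (series are centered and detrended upstream). The residual
#' covariance uses divisor `T - p`.
#'
#' @param series numeric `T x R` matrix for one patient.
#' @param p VAR order; requires `T - p > R * p` (otherwise the design is
#'   singular or has no residual degrees of freedom).
#' @return A list with `w` (coefficient vector, [coef_to_matrices()]
#'   convention), `Sigma` (`R x R` residual covariance), `residuals`
#'   (`(T-p) x R`), `R`, `p`.
#' @export
fit_var_mle <- function(series, p = 1L) {
  series <- as.matrix(series)
  T_len <- nrow(series)
  R <- ncol(series)
  if (T_len - p <= R * p) {
    stop("series too short for MLE VAR: T - p = ", T_len - p,
         " must exceed R * p = ", R * p)
  }
  d <- build_design(series, p)
  X <- t(d$H)                                  # T_eff x Rp
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular lagged design")
  B <- qr.coef(qrX, t(d$Y))                    # Rp x R, per-equation OLS
  A <- t(B)                                    # R x Rp
  E <- d$Y - A %*% d$H
  list(w = as.vector(A), Sigma = tcrossprod(E) / d$T_eff,
       residuals = t(E), R = R, p = p)
}

# h-step forecast-error covariances: Sum_{j<h} Psi_j Sigma Psi_j' with
# Psi_j the top-left R x R block of the j-th companion power.
forecast_error_covs <- function(matrices, Sigma, H) {
  R <- nrow(Sigma)
  p <- length(matrices)
  comp <- matrix(0, R * p, R * p)
  comp[1:R, ] <- do.call(cbind, matrices)
  if (p > 1) comp[(R + 1):(R * p), 1:(R * (p - 1))] <- diag(R * (p - 1))
  covs <- vector("list", H)
  Psi <- diag(R * p)
  acc <- matrix(0, R, R)
  for (h in seq_len(H)) {
    Pj <- Psi[1:R, 1:R, drop = FALSE]
    acc <- acc + Pj %*% Sigma %*% t(Pj)
    covs[[h]] <- acc
    Psi <- comp %*% Psi
  }
  covs
}

plugin_path <- function(A, last_obs, H, R, p) {
  lags <- last_obs                              # p x R, lag 1 first row
  out <- matrix(NA_real_, H, R)
  for (h in seq_len(H)) {
    yhat <- drop(A %*% as.vector(t(lags)))
    out[h, ] <- yhat
    if (p == 1) lags[1, ] <- yhat
    else lags <- rbind(yhat, lags[-p, , drop = FALSE])
  }
  out
}

#' Gaussian plug-in forecasts from an MLE VAR fit
#'
#' Recursive point forecasts with Gaussian forecast intervals from the
#' accumulated h-step forecast-error covariance (companion powers),
#' ignoring parameter uncertainty.
#'
#' @param fit a [fit_var_mle()] result.
#' @param last_obs the final `p` observations of the training series,
#'   newest last: a `p x R` matrix (or length-R vector for `p = 1`).
#' @param H forecast horizon.
#' @param level interval level (default 0.95).
#' @param patient_id,variable_names labels for the output frame.
#' @return A `bhvar_forecast` data.frame.
#' @export
mle_forecast <- function(fit, last_obs, H = 1L, level = 0.95,
                         patient_id = "p01",
                         variable_names = paste0("V", seq_len(fit$R))) {
  R <- fit$R
  p <- fit$p
  last_obs <- matrix(last_obs, ncol = R)
  stopifnot(nrow(last_obs) == p)
  lag_first <- last_obs[p:1, , drop = FALSE]    # newest-last -> lag-1 first
  A <- matrix(fit$w, nrow = R)
  pts <- plugin_path(A, lag_first, H, R, p)
  covs <- forecast_error_covs(coef_to_matrices(fit$w, R, p), fit$Sigma, H)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- t(matrix(vapply(covs, function(S) sqrt(pmax(diag(S), 0)),
                        numeric(R)), nrow = R))
  forecast_frame(patient_id, H, variable_names,
                 point = as.vector(t(pts)),
                 lo = as.vector(t(pts - z * se)),
                 hi = as.vector(t(pts + z * se)))
}

#' Per-patient elastic-net VAR regressions
#'
#' Fits, for each response variable, an elastic-net regression of the
#' current value on the previous `p` days of all variables (glmnet, mixing
#' weight 0.5, with intercept), choosing the penalty by k-fold
#' cross-validation with the one-standard-error rule (largest penalty whose
#' CV error is within one SE of the minimum) and refitting on all training
#' rows at that penalty.
#'
#' @param series numeric `T x R` matrix for one patient.
#' @param p VAR order; requires `T - p >= n_folds`.
#' @param n_folds CV folds (default 3).
#' @param seed seed for the random fold assignment.
#' @return A list with `intercepts` (length R), `A` (`R x Rp` coefficient
#'   matrix, [coef_to_matrices()] layout), `lambda` (chosen penalty per
#'   equation), `residuals` (`(T-p) x R`), `R`, `p`.
#' @export
fit_enet_patient <- function(series, p = 1L, n_folds = 3L, seed = 1L) {
  series <- as.matrix(series)
  T_len <- nrow(series)
  R <- ncol(series)
  d <- build_design(series, p)
  n_rows <- d$T_eff
  if (n_rows < n_folds) {
    stop("too few rows for ", n_folds, "-fold CV: T - p = ", n_rows)
  }
  X <- t(d$H)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), n_rows))
  intercepts <- numeric(R)
  A <- matrix(0, R, R * p)
  lambda <- numeric(R)
  resid <- matrix(NA_real_, n_rows, R)
  for (r in seq_len(R)) {
    y <- d$Y[r, ]
    cv <- glmnet::cv.glmnet(X, y, alpha = 0.5, foldid = foldid,
                            intercept = TRUE, family = "gaussian")
    lam <- cv$lambda.1se
    co <- as.vector(stats::coef(cv$glmnet.fit, s = lam))
    intercepts[r] <- co[1]
    A[r, ] <- co[-1]
    lambda[r] <- lam
    resid[, r] <- y - (intercepts[r] + X %*% A[r, ])
  }
  list(intercepts = intercepts, A = A, lambda = lambda, residuals = resid,
       R = R, p = p)
}

#' Residual-bootstrap forecasts from an elastic-net fit
#'
#' Recursive plug-in point forecasts (intercept + lag matrix); intervals
#' are percentile intervals over `B` bootstrap paths in which training
#' residual rows are resampled with replacement and added at every step.
#'
#' @param fit a [fit_enet_patient()] result.
#' @param last_obs the final `p` training observations, newest last
#'   (`p x R` matrix or length-R vector for `p = 1`).
#' @param H forecast horizon.
#' @param B bootstrap replicates (default 500).
#' @param level interval level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @param patient_id,variable_names labels for the output frame.
#' @return A `bhvar_forecast` data.frame.
#' @export
enet_forecast_bootstrap <- function(fit, last_obs, H = 1L, B = 500L,
                                    level = 0.95, seed = 1L,
                                    patient_id = "p01",
                                    variable_names = paste0("V", seq_len(fit$R))) {
  R <- fit$R
  p <- fit$p
  last_obs <- matrix(last_obs, ncol = R)
  stopifnot(nrow(last_obs) == p)
  lag_first <- last_obs[p:1, , drop = FALSE]
  step <- function(lags, noise) {
    drop(fit$A %*% as.vector(t(lags))) + fit$intercepts + noise
  }
  pts <- matrix(NA_real_, H, R)
  lags <- lag_first
  for (h in seq_len(H)) {
    yhat <- step(lags, 0)
    pts[h, ] <- yhat
    if (p == 1) lags[1, ] <- yhat
    else lags <- rbind(yhat, lags[-p, , drop = FALSE])
  }
  set.seed(seed)
  n_res <- nrow(fit$residuals)
  boots <- array(NA_real_, c(B, H, R))
  for (b in seq_len(B)) {
    lags <- lag_first
    for (h in seq_len(H)) {
      noise <- fit$residuals[sample.int(n_res, 1L), ]
      yhat <- step(lags, noise)
      boots[b, h, ] <- yhat
      if (p == 1) lags[1, ] <- yhat
      else lags <- rbind(yhat, lags[-p, , drop = FALSE])
    }
  }
  a <- (1 - level) / 2
  lo <- matrix(NA_real_, H, R)
  hi <- matrix(NA_real_, H, R)
  for (h in seq_len(H)) {
    for (r in seq_len(R)) {
      q <- stats::quantile(boots[, h, r], c(a, 1 - a), type = 7,
                           names = FALSE)
      lo[h, r] <- q[1]
      hi[h, r] <- q[2]
    }
  }
  forecast_frame(patient_id, H, variable_names,
                 point = as.vector(t(pts)),
                 lo = as.vector(t(lo)), hi = as.vector(t(hi)))
}

#' Forecast every patient of a panel with a per-patient baseline
#'
#' @param panel training [diary_panel].
#' @param H horizon.
#' @param method `"mle"` or `"enet"`.
#' @param p VAR order.
#' @param level interval level.
#' @param seed base seed (per-patient seeds are offset from it).
#' @param B bootstrap replicates for the elastic-net intervals.
#' @param ... passed to the per-patient fitter.
#' @return A `bhvar_forecast` data.frame covering all patients.
#' @export
baseline_forecast_panel <- function(panel, H = 1L, method = c("mle", "enet"),
                                    p = 1L, level = 0.95, seed = 1L,
                                    B = 500L, ...) {
  method <- match.arg(method)
  out <- lapply(seq_along(panel$patients), function(i) {
    ps <- panel$patients[[i]]
    T_len <- nrow(ps$values)
    last_obs <- ps$values[(T_len - p + 1):T_len, , drop = FALSE]
    if (method == "mle") {
      fit <- fit_var_mle(ps$values, p = p, ...)
      mle_forecast(fit, last_obs, H = H, level = level,
                   patient_id = ps$patient_id,
                   variable_names = panel$variable_names)
    } else {
      fit <- fit_enet_patient(ps$values, p = p, seed = seed + i, ...)
      enet_forecast_bootstrap(fit, last_obs, H = H, B = B, level = level,
                              seed = seed + 1000L + i,
                              patient_id = ps$patient_id,
                              variable_names = panel$variable_names)
    }
  })
  res <- do.call(rbind, out)
  class(res) <- c("bhvar_forecast", "data.frame")
  res
}
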