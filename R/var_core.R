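#' Build the stacked VAR(p) design for one series
#'
#' For a `T x R` series and order `p`, the response stacks the observations
#' at times `p+1, ..., T` and the regressor matrix `H` holds, in column
#' `t - p`, the lagged vectors `(y[t-1]; y[t-2]; ...; y[t-p])`. The layout is
#' chosen so that with the coefficient vectorization of
#' [coef_to_matrices()], `(t(H) %x% I_R) %*% w` reproduces
#' `sum_i A_i y[t-i]` column by column.
#'
#' @param series numeric `T x R` matrix (one patient, complete).
#' @param p VAR order (`T > p` required).
#' @return A list with elements `Y` (`R x (T-p)` response matrix), `H`
#'   (`Rp x (T-p)` regressors), `y` (stacked response vector of length
#'   `(T-p) * R`), `R`, `p`, `T_eff = T - p`, and the precomputed cross
#'   products `G = H %*% t(H)` and `C = Y %*% t(H)` used by the sampler.
#' @export
build_design <- function(series, p) {
  series <- as.matrix(series)
  T_len <- nrow(series)
  R <- ncol(series)
  p <- as.integer(p)
  if (T_len <= p) stop("series length ", T_len, " must exceed order ", p)
  if (anyNA(series)) stop("design requires a complete (imputed) series")
  T_eff <- T_len - p
  Y <- t(series[(p + 1):T_len, , drop = FALSE])        # R x T_eff
  H <- matrix(0, R * p, T_eff)
  for (i in seq_len(p)) {
    rows <- ((i - 1) * R + 1):(i * R)
    H[rows, ] <- t(series[(p + 1 - i):(T_len - i), , drop = FALSE])
  }
  list(Y = Y, H = H, y = as.vector(Y), R = R, p = p, T_eff = T_eff,
       G = H %*% t(H), C = Y %*% t(H))
}

#' Build designs for every patient of a panel
#'
#' @param panel a preprocessed [diary_panel] (no missing values).
#' @param p VAR order.
#' @return A list of per-patient designs (see [build_design()]) named by
#'   patient id, with attributes `R` and `p`.
#' @export
build_designs <- function(panel, p) {
  designs <- lapply(panel$patients, function(ps) build_design(ps$values, p))
  attr(designs, "R") <- length(panel$variable_names)
  attr(designs, "p") <- as.integer(p)
  attr(designs, "Gsum") <- Reduce(`+`, lapply(designs, `[[`, "G"))
  designs
}

#' Convert between a coefficient vector and lag matrices
#'
#' The model's coefficient vector is `w = vec([A_1, ..., A_p])`: the `R x R`
#' lag matrices are concatenated horizontally and vectorized column-major.
#' All modules share this convention through these two functions.
#'
#' @param w numeric vector of length `R^2 * p`.
#' @param R number of variables.
#' @param p VAR order.
#' @return `coef_to_matrices`: a list of `p` matrices, each `R x R`.
#' @export
coef_to_matrices <- function(w, R, p) {
  if (length(w) != R * R * p) {
    stop("coefficient length ", length(w), " != R^2 * p = ", R * R * p)
  }
  A <- matrix(w, nrow = R)                    # R x (R p)
  lapply(seq_len(p), function(i) A[, ((i - 1) * R + 1):(i * R), drop = FALSE])
}

#' @rdname coef_to_matrices
#' @param matrices list of `p` `R x R` lag matrices.
#' @return `matrices_to_coef`: the vector `vec([A_1, ..., A_p])`.
#' @export
matrices_to_coef <- function(matrices) {
  as.vector(do.call(cbind, matrices))
}

#' Spectral radius of the VAR companion matrix
#'
#' The VAR(p) is stable (stationary) iff the spectral radius of its
#' `Rp x Rp` companion matrix is below 1.
#'
#' @param matrices list of `p` `R x R` lag matrices.
#' @return Nonnegative real: the largest eigenvalue modulus.
#' @export
companion_spectral_radius <- function(matrices) {
  p <- length(matrices)
  R <- nrow(matrices[[1]])
  comp <- matrix(0, R * p, R * p)
  comp[1:R, ] <- do.call(cbind, matrices)
  if (p > 1) {
    comp[(R + 1):(R * p), 1:(R * (p - 1))] <- diag(R * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Gaussian VAR log likelihood over a set of patients
#'
#' Sums, over patients and time, the MVN(0, solve(Lambda)) log density of
#' the one-step residuals `y_t - sum_i A_i y_{t-i}`.
#'
#' @param designs output of [build_designs()] (or a list of designs).
#' @param coefs a single coefficient vector shared by all patients, or a
#'   list/matrix of per-patient coefficient vectors (rows or elements in
#'   design order).
#' @param Lambda `R x R` symmetric positive-definite innovation precision.
#' @return The total log likelihood (a scalar).
#' @export
var_log_likelihood <- function(designs, coefs, Lambda) {
  R <- nrow(Lambda)
  ch <- tryCatch(chol(Lambda), error = function(e) {
    stop("Lambda is not positive definite")
  })
  logdet <- 2 * sum(log(diag(ch)))
  ll <- 0
  for (n in seq_along(designs)) {
    d <- designs[[n]]
    wn <- if (is.list(coefs)) coefs[[n]]
          else if (is.matrix(coefs)) coefs[n, ]
          else coefs
    A <- matrix(wn, nrow = d$R)
    E <- d$Y - A %*% d$H
    q <- sum((ch %*% E)^2)
    ll <- ll + 0.5 * d$T_eff * (logdet - R * log(2 * pi)) - 0.5 * q
  }
  ll
}

#' Akaike information criterion
#'
#' @param loglik maximized (or plug-in) log likelihood.
#' @param n_params number of parameters (>= 1).
#' @return `2 * n_params - 2 * loglik`.
#' @export
aic <- function(loglik, n_params) {
  stopifnot(n_params >= 1)
  2 * n_params - 2 * loglik
}

#' Parameter count for the hierarchical VAR fit
#'
#' Counts population and patient coefficient vectors (`R^2 p * (N + 1)`),
#' the free entries of the innovation precision (`R (R + 1) / 2`) and the
#' five per-coefficient hyperparameter vectors (`5 R^2 p`: the L1 and L2
#' weights, the latent elastic-net scales, the deviation precisions and the
#' expansion factors).
#'
#' @param R number of variables.
#' @param p VAR order.
#' @param N number of patients.
#' @return Integer parameter count.
#' @export
hier_param_count <- function(R, p, N) {
  K <- R * R * p
  K * (N + 1) + R * (R + 1) / 2 + 5 * K
}
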