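# Full-conditional updates for the parameter-expanded Gibbs sampler.
#
# Notation: per patient n the likelihood is y_n = (t(H_n) %x% I_R) w_n + e_n
# with w_n = w + alpha * v_n (elementwise product) and stacked error
# precision I %x% Lambda.  Using vec identities everything reduces to the
# small cross products G_n = H H^T (Rp x Rp) and C_n = Y H^T (R x Rp)
# precomputed in build_design(), so each conditional is assembled from
# K x K = (R^2 p)^2 matrices regardless of series length.

# Draw from MVN with precision P and linear term b: density
# proportional to exp(-x' P x / 2 + b' x).  Returns list(draw, mean).
# P is symmetrized; on Cholesky failure a 1e-10 ridge is added (counted
# by the caller via the "jittered" flag).
mvn_from_canonical <- function(P, b, draw = TRUE) {
  P <- (P + t(P)) / 2
  jittered <- FALSE
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(ch)) {
    jittered <- TRUE
    ch <- tryCatch(chol(P + 1e-10 * diag(nrow(P))), error = function(e) NULL)
    if (is.null(ch)) stop("conditional precision not positive definite")
  }
  m <- backsolve(ch, forwardsolve(t(ch), b))
  x <- if (draw) m + backsolve(ch, stats::rnorm(length(b))) else m
  list(draw = x, mean = m, jittered = jittered)
}

# Canonical parameters (P, b) of the w | rest conditional.
cond_w <- function(state, designs) {
  R <- state$R
  Lam <- state$Lambda
  Gsum <- attr(designs, "Gsum")
  if (is.null(Gsum)) Gsum <- Reduce(`+`, lapply(designs, `[[`, "G"))
  Macc <- 0
  for (n in seq_along(designs)) {
    d <- designs[[n]]
    U <- matrix(state$alpha * state$v[n, ], nrow = R)
    Macc <- Macc + (d$C - U %*% d$G)
  }
  D <- state$lam2 + 1 / state$two_tau2
  P <- kronecker(Gsum, Lam) + diag(D, state$K)
  b <- as.vector(Lam %*% Macc)
  list(P = P, b = b)
}

upd_w <- function(state, designs) {
  cw <- cond_w(state, designs)
  res <- mvn_from_canonical(cw$P, cw$b)
  if (res$jittered) state$jitter_count <- state$jitter_count + 1L
  state$w <- res$draw
  state
}

# Per-patient quantities shared by the v_n and alpha conditionals at the
# current (w, Lambda): GL_n = G_n %x% Lambda and the precision-weighted
# residual term RW_n = vec(Lambda (C_n - W G_n)).
sweep_precompute <- function(state, designs) {
  R <- state$R
  Lam <- state$Lambda
  W <- matrix(state$w, nrow = R)
  GL <- vector("list", length(designs))
  RW <- vector("list", length(designs))
  for (n in seq_along(designs)) {
    d <- designs[[n]]
    GL[[n]] <- kronecker(d$G, Lam)
    RW[[n]] <- as.vector(Lam %*% (d$C - W %*% d$G))
  }
  list(GL = GL, RW = RW)
}

# Canonical parameters of v_n | rest for one patient.
cond_v_n <- function(state, designs, n, pre = NULL) {
  if (is.null(pre)) pre <- sweep_precompute(state, designs)
  P <- pre$GL[[n]] * tcrossprod(state$alpha) + diag(state$theta_v, state$K)
  b <- state$alpha * pre$RW[[n]]
  list(P = P, b = b)
}

upd_v <- function(state, designs, pre = NULL) {
  if (is.null(pre)) pre <- sweep_precompute(state, designs)
  for (n in seq_len(state$N)) {
    cv <- cond_v_n(state, designs, n, pre)
    res <- mvn_from_canonical(cv$P, cv$b)
    if (res$jittered) state$jitter_count <- state$jitter_count + 1L
    state$v[n, ] <- res$draw
  }
  state
}

# Canonical parameters of alpha | rest.
cond_alpha <- function(state, designs, hyper, pre = NULL) {
  if (is.null(pre)) pre <- sweep_precompute(state, designs)
  P <- diag(1 / hyper$alpha_prior_var, state$K)
  b <- numeric(state$K)
  for (n in seq_along(designs)) {
    vn <- state$v[n, ]
    P <- P + pre$GL[[n]] * tcrossprod(vn)
    b <- b + vn * pre$RW[[n]]
  }
  list(P = P, b = b)
}

upd_alpha <- function(state, designs, hyper, pre = NULL) {
  ca <- cond_alpha(state, designs, hyper, pre)
  res <- mvn_from_canonical(ca$P, ca$b)
  if (res$jittered) state$jitter_count <- state$jitter_count + 1L
  state$alpha <- res$draw
  state
}

# log of the xi^2-mediated factor of the Lambda conditional: the
# Exp(lam1sq / (2 xi^2)) prior on the latent scales depends on Lambda
# through xi^2, contributing  prod_k (1 / xi2_k) exp(-lam1sq_k u_k /
# (2 xi2_k))  on top of the conjugate Wishart form.
lambda_xi2_logfactor <- function(Lambda, state) {
  xi2 <- compute_xi2(Lambda, state$R, state$p)
  -sum(log(xi2)) - sum(state$lam1sq * state$two_tau2 / (2 * xi2))
}

# Conjugate Wishart part of the Lambda conditional (prior + Gaussian
# residual likelihood), used as the independence-Metropolis proposal.
lambda_conjugate_part <- function(state, designs, hyper) {
  R <- state$R
  S <- matrix(0, R, R)
  T_tot <- 0
  W <- matrix(state$w, nrow = R)
  for (n in seq_along(designs)) {
    d <- designs[[n]]
    A <- W + matrix(state$alpha * state$v[n, ], nrow = R)
    E <- d$Y - A %*% d$H
    S <- S + tcrossprod(E)
    T_tot <- T_tot + d$T_eff
  }
  df <- hyper$wishart_dof + T_tot
  scale <- solve(hyper$K_scale_inv + S)
  scale <- (scale + t(scale)) / 2
  list(df = df, scale = scale)
}

upd_Lambda <- function(state, designs, hyper) {
  part <- lambda_conjugate_part(state, designs, hyper)
  if (part$df <= state$R - 1) {
    stop("Wishart degrees of freedom ", part$df,
         " too small for R = ", state$R)
  }
  prop <- stats::rWishart(1, part$df, part$scale)[, , 1]
  prop <- (prop + t(prop)) / 2
  state$lambda_proposals <- state$lambda_proposals + 1L
  log_ratio <- lambda_xi2_logfactor(prop, state) -
    lambda_xi2_logfactor(state$Lambda, state)
  if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
    state$Lambda <- prop
    state$xi2 <- compute_xi2(prop, state$R, state$p)
    state$lambda_accepts <- state$lambda_accepts + 1L
  }
  state
}

# Numerical guard band for the positive scalar blocks: keeps reciprocals,
# rates and their products finite without influencing any realistically
# reachable value.
POS_LO <- 1e-12
POS_HI <- 1e12

# Univariate slice sampler with stepping-out and shrinkage (Neal 2003).
# logf must be finite at x0; non-finite evaluations elsewhere are treated
# as log(0).
slice_sample_1d <- function(x0, logf_raw, w = 1, max_step = 50L) {
  logf <- function(x) {
    v <- logf_raw(x)
    if (is.finite(v)) v else -Inf
  }
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  logy <- f0 + log(stats::runif(1))
  L <- x0 - w * stats::runif(1)
  U <- L + w
  k <- max_step
  while (k > 0 && logf(L) > logy) {
    L <- L - w
    k <- k - 1
  }
  k <- max_step
  while (k > 0 && logf(U) > logy) {
    U <- U + w
    k <- k - 1
  }
  repeat {
    x1 <- L + stats::runif(1) * (U - L)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else U <- x1
    if (U - L < 1e-12) return(x0)
  }
}

# 2 tau^2_k | rest, slice-sampled on the log scale.  Unnormalized density
# in u = 2 tau^2:  (lam2 + 1/u)^(1/2) exp(-w_k^2 / (2u)) exp(-rho u) with
# rho = lam1sq / (2 xi^2).
upd_two_tau2 <- function(state) {
  rho <- state$lam1sq / (2 * state$xi2)
  for (k in seq_len(state$K)) {
    wk2 <- state$w[k]^2
    l2 <- state$lam2[k]
    rk <- rho[k]
    logf <- function(s) {
      u <- exp(s)
      0.5 * log1p(l2 * u) - 0.5 * s - wk2 / (2 * u) - rk * u + s
    }
    s1 <- slice_sample_1d(log(state$two_tau2[k]), logf)
    state$two_tau2[k] <- min(max(exp(s1), POS_LO), POS_HI)
  }
  state
}

# lam1sq_k | rest.  Under the default prior on the squared L1 weight the
# conditional is exactly Gamma(shape + 1, rate + u_k / (2 xi2_k)); under
# the prior on the L1 weight itself it is slice-sampled on log(lambda1).
upd_lam1 <- function(state, hyper) {
  a <- hyper$lam1_shape_rate["shape"]
  b <- hyper$lam1_shape_rate["rate"]
  if (hyper$l1_prior_on == "lambda1_sq") {
    state$lam1sq <- pmin(pmax(stats::rgamma(state$K, a + 1,
                                            b + state$two_tau2 /
                                              (2 * state$xi2)),
                              POS_LO), POS_HI)
  } else {
    for (k in seq_len(state$K)) {
      cu <- state$two_tau2[k] / (2 * state$xi2[k])
      logf <- function(s) (a + 2) * s - b * exp(s) - cu * exp(2 * s)
      s1 <- slice_sample_1d(0.5 * log(state$lam1sq[k]), logf)
      state$lam1sq[k] <- min(max(exp(2 * s1), POS_LO), POS_HI)
    }
  }
  state
}

# lam2_k | rest, slice-sampled on the log scale.  Unnormalized density:
# lam2^(a-1) (lam2 + 1/u)^(1/2) exp(-(b + w_k^2 / 2) lam2).
upd_lam2 <- function(state, hyper) {
  a <- hyper$lam2_shape_rate["shape"]
  b <- hyper$lam2_shape_rate["rate"]
  for (k in seq_len(state$K)) {
    uk <- state$two_tau2[k]
    ck <- b + state$w[k]^2 / 2
    logf <- function(s) a * s + 0.5 * log(exp(s) + 1 / uk) - ck * exp(s)
    s1 <- slice_sample_1d(log(state$lam2[k]), logf)
    state$lam2[k] <- min(max(exp(s1), POS_LO), POS_HI)
  }
  state
}

# theta_vk | rest: conjugate Gamma given the deviations.
upd_theta_v <- function(state, hyper) {
  a <- hyper$theta_shape_rate["shape"]
  b <- hyper$theta_shape_rate["rate"]
  ssq <- colSums(state$v^2)
  state$theta_v <- pmin(pmax(stats::rgamma(state$K, a + state$N / 2,
                                           b + ssq / 2),
                             POS_LO), POS_HI)
  state
}

#' One full scan of the parameter-expanded Gibbs sampler
#'
#' Updates, in fixed order: the population coefficients `w` (conjugate MVN
#' under the elastic-net prior), each patient deviation `v_n` (conjugate
#' MVN with the expansion factors absorbed into the regressors), the
#' expansion vector `alpha` (conjugate MVN under its diffuse prior), the
#' innovation precision `Lambda` (independence Metropolis step with the
#' conjugate Wishart as proposal and the scale-prior factor mediated by the
#' conditional variances `xi^2` in the acceptance ratio), the latent
#' elastic-net scales `2 tau^2_k` (slice), the L1 weights (conjugate Gamma
#' on the squared scale by default), the L2 weights (slice) and the
#' deviation precisions `theta_vk` (conjugate Gamma). Uses R's global RNG;
#' seed with `set.seed()` for reproducibility.
#'
#' @param state a `bhvar_state` (see [init_state()]).
#' @param designs output of [build_designs()].
#' @param hyper a [hyper_params()] object.
#' @return The updated `bhvar_state`.
#' @export
gibbs_sweep <- function(state, designs, hyper) {
  state <- upd_w(state, designs)
  pre <- sweep_precompute(state, designs)
  state <- upd_v(state, designs, pre)
  state <- upd_alpha(state, designs, hyper, pre)
  state <- upd_Lambda(state, designs, hyper)
  state <- upd_two_tau2(state)
  state <- upd_lam1(state, hyper)
  state <- upd_lam2(state, hyper)
  state <- upd_theta_v(state, hyper)
  state
}
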