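#' Hyperparameters of the hierarchical elastic-net VAR
#'
#' Gamma hyperpriors use a (mean, degrees-of-freedom) parameterization by
#' default: `Gamma(mean m, dof d)` has shape `d/2` and rate `d/(2m)`, so a
#' small `d` gives a near-flat prior with the stated mean. Set
#' `gamma_param = "shape_rate"` to pass shapes and rates directly (the
#' `mu*`/`k_theta` slots then hold shapes and the `nu*`/`s_theta` slots
#' rates).
#'
#' Defaults are the weakly informative choices used throughout the package:
#' squared L1 weights `Gamma(1, 0.001)`, L2 weights `Gamma(1, 0.01)`,
#' deviation precisions `Gamma(1, 0.01)`, innovation precision
#' `Wishart((R-1) I_R, 1)` (scale such that the prior mean is
#' `dof * K_scale`; for `R = 1` the scale defaults to 1 since `R - 1`
#' degenerates), and expansion factors `MVN(0, 100 I)`.
#'
#' @param R number of variables.
#' @param p VAR order.
#' @param mu1,nu1 Gamma mean/dof for the squared L1 weights (or for the L1
#'   weights themselves when `l1_prior_on = "lambda1"`).
#' @param mu2,nu2 Gamma mean/dof for the L2 weights.
#' @param k_theta,s_theta Gamma mean/dof for the deviation precisions.
#' @param K_scale `R x R` Wishart scale matrix for the innovation precision.
#' @param wishart_dof Wishart degrees of freedom.
#' @param alpha_prior_var prior variance of each expansion factor.
#' @param gamma_param `"mean_dof"` (default) or `"shape_rate"`.
#' @param l1_prior_on whether the Gamma prior sits on the squared L1 weight
#'   (`"lambda1_sq"`, default, conjugate) or on the L1 weight itself
#'   (`"lambda1"`, slice-sampled).
#' @return An object of class `bhvar_hyper`.
#' @export
hyper_params <- function(R, p = 1L,
                         mu1 = 1, nu1 = 0.001,
                         mu2 = 1, nu2 = 0.01,
                         k_theta = 1, s_theta = 0.01,
                         K_scale = NULL, wishart_dof = 1,
                         alpha_prior_var = 100,
                         gamma_param = c("mean_dof", "shape_rate"),
                         l1_prior_on = c("lambda1_sq", "lambda1")) {
  gamma_param <- match.arg(gamma_param)
  l1_prior_on <- match.arg(l1_prior_on)
  if (is.null(K_scale)) {
    K_scale <- if (R > 1) (R - 1) * diag(R) else matrix(1, 1, 1)
  }
  K_scale <- as.matrix(K_scale)
  stopifnot(nrow(K_scale) == R, isSymmetric(unname(K_scale)),
            all(eigen(K_scale, only.values = TRUE)$values > 0),
            wishart_dof > 0, alpha_prior_var > 0,
            mu1 > 0, nu1 > 0, mu2 > 0, nu2 > 0, k_theta > 0, s_theta > 0)
  sr <- function(m, d) {
    if (gamma_param == "mean_dof") c(shape = d / 2, rate = d / (2 * m))
    else c(shape = m, rate = d)
  }
  structure(list(R = as.integer(R), p = as.integer(p),
                 mu1 = mu1, nu1 = nu1, mu2 = mu2, nu2 = nu2,
                 k_theta = k_theta, s_theta = s_theta,
                 K_scale = K_scale, wishart_dof = wishart_dof,
                 alpha_prior_var = alpha_prior_var,
                 gamma_param = gamma_param, l1_prior_on = l1_prior_on,
                 lam1_shape_rate = sr(mu1, nu1),
                 lam2_shape_rate = sr(mu2, nu2),
                 theta_shape_rate = sr(k_theta, s_theta),
                 K_scale_inv = solve(K_scale)),
            class = "bhvar_hyper")
}

#' Conditional variances of the elastic-net scale prior
#'
#' With `M = I_{Rp} %x% solve(Lambda)`, returns for each coordinate `k` the
#' conditional variance of coordinate `k` given coordinates `k+1, ...,
#' R^2 p` under covariance `M` (a Schur complement). Because `M` is block
#' diagonal with identical `R x R` blocks, the pattern of within-block
#' sequential conditional variances repeats across the `Rp` blocks.
#'
#' @param Lambda `R x R` symmetric positive-definite precision matrix.
#' @param R number of variables.
#' @param p VAR order.
#' @return A strictly positive vector of length `R^2 p`.
#' @export
compute_xi2 <- function(Lambda, R, p) {
  Lambda <- as.matrix(Lambda)
  stopifnot(nrow(Lambda) == R)
  ev <- eigen((Lambda + t(Lambda)) / 2, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Lambda is not positive definite")
  Sigma <- solve(Lambda)
  block <- vapply(seq_len(R), function(j) {
    if (j == R) return(Sigma[R, R])
    trail <- (j + 1):R
    Sigma[j, j] - drop(Sigma[j, trail, drop = FALSE] %*%
                         solve(Sigma[trail, trail, drop = FALSE],
                               Sigma[trail, j]))
  }, numeric(1))
  rep(block, R * p)
}

# Prior draws truncated to a sane band: under the near-flat defaults an
# unconstrained prior draw routinely under/overflows, so starting values
# are drawn from the prior conditioned on [lo, hi] by inverse-CDF.
rgamma_trunc <- function(n, shape, rate, lo = 1e-4, hi = 1e4) {
  plo <- stats::pgamma(lo, shape, rate)
  phi <- stats::pgamma(hi, shape, rate)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qgamma(u, shape, rate), lo), hi)
}
rexp_trunc <- function(n, rate, lo = 1e-4, hi = 1e4) {
  plo <- stats::pexp(lo, rate)
  phi <- stats::pexp(hi, rate)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qexp(u, rate), lo), hi)
}

#' Initialize the Gibbs sampler state
#'
#' Population and deviation coefficients start at 0, expansion factors at 1,
#' the innovation precision at the (diagonal-loaded) sample precision of the
#' pooled responses, and the positive scalar blocks are drawn from their
#' priors truncated to `[1e-4, 1e4]` (avoiding degenerate starting values
#' under the near-flat defaults). Deterministic given `seed`.
#'
#' @param hyper a [hyper_params()] object.
#' @param designs output of [build_designs()].
#' @param seed integer RNG seed.
#' @return A `bhvar_state` list holding `w`, `v` (`N x K`), `alpha`,
#'   `Lambda`, `two_tau2`, `lam1sq`, `lam2`, `theta_v`, `xi2`, bookkeeping
#'   counters, and the shape constants `R`, `p`, `K`, `N`.
#' @export
init_state <- function(hyper, designs, seed = 1L) {
  R <- hyper$R
  p <- hyper$p
  K <- R * R * p
  N <- length(designs)
  set.seed(seed)
  pooled <- do.call(cbind, lapply(designs, `[[`, "Y"))
  Lambda <- if (ncol(pooled) > R) {
    S <- stats::cov(t(pooled))
    solve(S + 0.1 * diag(R))
  } else {
    diag(R)
  }
  Lambda <- (Lambda + t(Lambda)) / 2
  xi2 <- compute_xi2(Lambda, R, p)
  lam1sq <- rgamma_trunc(K, hyper$lam1_shape_rate["shape"],
                         hyper$lam1_shape_rate["rate"])
  if (hyper$l1_prior_on == "lambda1") lam1sq <- lam1sq^2
  lam2 <- rgamma_trunc(K, hyper$lam2_shape_rate["shape"],
                       hyper$lam2_shape_rate["rate"])
  theta_v <- rgamma_trunc(K, hyper$theta_shape_rate["shape"],
                          hyper$theta_shape_rate["rate"])
  two_tau2 <- rexp_trunc(K, rate = lam1sq / (2 * xi2))
  structure(list(w = numeric(K), v = matrix(0, N, K), alpha = rep(1, K),
                 Lambda = Lambda, two_tau2 = two_tau2, lam1sq = lam1sq,
                 lam2 = lam2, theta_v = theta_v, xi2 = xi2,
                 R = R, p = p, K = K, N = N,
                 jitter_count = 0L, lambda_proposals = 0L,
                 lambda_accepts = 0L),
            class = "bhvar_state")
}
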