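# Shared test utilities: two-sample Kolmogorov-Smirnov checks against
# closed-form or numerically integrated reference distributions, and the
# scalar (R = 1, p = 1, N = 1, T = 6) fixture used by the
# conditional-sampler oracles.

# Two-sample KS statistic and its critical value at significance alpha.
ks2_stat <- function(x, y) {
  unname(suppressWarnings(stats::ks.test(x, y)$statistic))
}
ks2_crit <- function(n, m, alpha = 0.001) {
  sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
}
expect_ks_match <- function(draws, reference, alpha = 0.001) {
  D <- ks2_stat(draws, reference)
  expect_lt(D, ks2_crit(length(draws), length(reference), alpha))
}

# i.i.d. sampling from an unnormalized log-density on a grid by
# inverse-CDF with within-cell uniform jitter.  Used as the independent
# reference for conditionals without a named form.
sample_logdensity <- function(logf, lower, upper, m, n_grid = 4096L) {
  xs <- seq(lower, upper, length.out = n_grid)
  lf <- vapply(xs, logf, numeric(1))
  lf[!is.finite(lf)] <- -Inf
  f <- exp(lf - max(lf))
  dx <- xs[2] - xs[1]
  cdf <- cumsum(f) * dx
  total <- cdf[n_grid]
  stopifnot(total > 0, f[n_grid] / max(f) < 1e-8)  # upper tail covered
  u <- stats::runif(m) * total
  idx <- findInterval(u, cdf) + 1L
  idx[idx > n_grid] <- n_grid
  xs[idx] - stats::runif(m) * dx
}

# Scalar fixture: one patient, one variable, T = 6, order 1, with every
# block of the sampler state frozen at a hand-picked value.  Hyper uses
# the shape/rate Gamma parameterization so the reference densities are
# explicit.
scalar_fixture <- function() {
  set.seed(42)
  y <- numeric(6)
  y[1] <- stats::rnorm(1)
  for (t in 2:6) y[t] <- 0.7 * y[t - 1] + 0.5 * stats::rnorm(1)
  d <- build_design(matrix(y, ncol = 1), p = 1)
  designs <- list(p01 = d)
  attr(designs, "R") <- 1L
  attr(designs, "p") <- 1L
  attr(designs, "Gsum") <- d$G
  hyper <- hyper_params(R = 1, p = 1, gamma_param = "shape_rate",
                        mu1 = 1.2, nu1 = 0.9,     # lam1sq ~ Gamma(1.2, 0.9)
                        mu2 = 1.1, nu2 = 0.8,     # lam2 ~ Gamma(1.1, 0.8)
                        k_theta = 2, s_theta = 2, # theta ~ Gamma(2, 2)
                        K_scale = matrix(1, 1, 1), wishart_dof = 2,
                        alpha_prior_var = 100)
  state <- init_state(hyper, designs, seed = 1)
  state$w <- 0.3
  state$v <- matrix(0.15, 1, 1)
  state$alpha <- 1.2
  state$Lambda <- matrix(2, 1, 1)
  state$xi2 <- compute_xi2(state$Lambda, 1, 1)   # = 0.5
  state$two_tau2 <- 0.8
  state$lam1sq <- 4
  state$lam2 <- 1.5
  state$theta_v <- 2.5
  list(y = y, designs = designs, hyper = hyper, state = state)
}

# Small complete panels for module tests.
toy_panel <- function(N = 2, T_len = 8, R = 2, seed = 1) {
  set.seed(seed)
  patients <- lapply(seq_len(N), function(n) {
    patient_series(sprintf("p%02d", n), seq_len(T_len),
                   matrix(stats::rnorm(T_len * R), T_len, R))
  })
  diary_panel(patients, paste0("V", seq_len(R)))
}
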