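# Oracle checks for every full-conditional update on the scalar model
# (R = 1, p = 1, N = 1, T = 6): each sampler's output is compared against
# a closed-form conjugate density or a normalized 1-D numeric integration
# of prior x likelihood via a two-sample Kolmogorov-Smirnov statistic at
# the 0.1% critical value.  Slice and Metropolis updates are thinned so
# the KS independence assumption is reasonable.

n_ks <- 10000L

chain_of <- function(state, step, extract, n, thin = 1L) {
  out <- numeric(n)
  for (i in seq_len(n * thin)) {
    state <- step(state)
    if (i %% thin == 0L) out[i / thin] <- extract(state)
  }
  out
}

test_that("population-coefficient conditional matches its conjugate normal", {
  fx <- scalar_fixture()
  st <- fx$state
  d <- fx$designs[[1]]
  u_dev <- st$alpha * st$v[1, 1]
  prec <- drop(st$Lambda) * d$G[1, 1] + (st$lam2 + 1 / st$two_tau2)
  mean_w <- drop(st$Lambda) * (d$C[1, 1] - u_dev * d$G[1, 1]) / prec

  cw <- bhvar:::cond_w(st, fx$designs)
  expect_equal(drop(cw$P), prec, tolerance = 1e-12)
  expect_equal(drop(cw$b) / drop(cw$P), mean_w, tolerance = 1e-12)

  set.seed(101)
  draws <- chain_of(st, function(s) bhvar:::upd_w(s, fx$designs),
                    function(s) s$w, n_ks)
  ref <- rnorm(n_ks, mean_w, 1 / sqrt(prec))
  expect_ks_match(draws, ref)
})

test_that("deviation and expansion conditionals match their conjugate normals", {
  fx <- scalar_fixture()
  st <- fx$state
  d <- fx$designs[[1]]
  Lam <- drop(st$Lambda)
  resid_term <- d$C[1, 1] - st$w * d$G[1, 1]

  prec_v <- st$alpha^2 * Lam * d$G[1, 1] + st$theta_v
  mean_v <- st$alpha * Lam * resid_term / prec_v
  set.seed(102)
  draws_v <- chain_of(st, function(s) bhvar:::upd_v(s, fx$designs),
                      function(s) s$v[1, 1], n_ks)
  expect_ks_match(draws_v, rnorm(n_ks, mean_v, 1 / sqrt(prec_v)))

  prec_a <- st$v[1, 1]^2 * Lam * d$G[1, 1] + 1 / fx$hyper$alpha_prior_var
  mean_a <- st$v[1, 1] * Lam * resid_term / prec_a
  set.seed(103)
  draws_a <- chain_of(st, function(s) bhvar:::upd_alpha(s, fx$designs,
                                                        fx$hyper),
                      function(s) s$alpha, n_ks)
  expect_ks_match(draws_a, rnorm(n_ks, mean_a, 1 / sqrt(prec_a)))
})

test_that("innovation-precision update targets Wishart x scale-prior factor", {
  fx <- scalar_fixture()
  st <- fx$state
  d <- fx$designs[[1]]
  # scalar closed form: Gamma with the xi^2-mediated factor absorbed
  resid <- d$Y - (st$w + st$alpha * st$v[1, 1]) * d$H
  S <- sum(resid^2)
  shape <- (fx$hyper$wishart_dof + d$T_eff) / 2 + 1
  rate <- fx$hyper$K_scale_inv[1, 1] / 2 + S / 2 +
    st$lam1sq * st$two_tau2 / 2
  set.seed(104)
  draws <- chain_of(st, function(s) bhvar:::upd_Lambda(s, fx$designs,
                                                       fx$hyper),
                    function(s) drop(s$Lambda), n_ks, thin = 5L)
  expect_ks_match(draws, rgamma(n_ks, shape, rate))
})

test_that("latent-scale conditional matches numeric integration", {
  fx <- scalar_fixture()
  st <- fx$state
  rho <- drop(st$lam1sq / (2 * st$xi2))
  wk2 <- st$w^2
  l2 <- st$lam2
  logf_u <- function(u) {
    if (u <= 0) return(-Inf)
    0.5 * log(l2 + 1 / u) - wk2 / (2 * u) - rho * u
  }
  set.seed(105)
  ref <- sample_logdensity(logf_u, 1e-6, 15, n_ks)
  draws <- chain_of(st, function(s) bhvar:::upd_two_tau2(s),
                    function(s) s$two_tau2, n_ks, thin = 10L)
  expect_ks_match(draws, ref)
})

test_that("L1-weight conditional is the derived conjugate Gamma", {
  fx <- scalar_fixture()
  st <- fx$state
  a <- fx$hyper$lam1_shape_rate["shape"]
  b <- fx$hyper$lam1_shape_rate["rate"]
  # independent numeric check of the conjugacy derivation: prior x
  # Exp(lam1sq/(2 xi2)) likelihood for the latent scale
  logf <- function(s) {
    if (s <= 0) return(-Inf)
    (a - 1) * log(s) - b * s + log(s) - s * st$two_tau2 / (2 * st$xi2)
  }
  set.seed(106)
  ref_numeric <- sample_logdensity(logf, 1e-8, 60, n_ks)
  draws <- chain_of(st, function(s) bhvar:::upd_lam1(s, fx$hyper),
                    function(s) s$lam1sq, n_ks)
  expect_ks_match(draws, ref_numeric)
})

test_that("L2-weight conditional matches numeric integration", {
  fx <- scalar_fixture()
  st <- fx$state
  a <- fx$hyper$lam2_shape_rate["shape"]
  b <- fx$hyper$lam2_shape_rate["rate"]
  logf <- function(l2) {
    if (l2 <= 0) return(-Inf)
    (a - 1) * log(l2) + 0.5 * log(l2 + 1 / st$two_tau2) -
      (b + st$w^2 / 2) * l2
  }
  set.seed(107)
  ref <- sample_logdensity(logf, 1e-8, 40, n_ks)
  draws <- chain_of(st, function(s) bhvar:::upd_lam2(s, fx$hyper),
                    function(s) s$lam2, n_ks, thin = 10L)
  expect_ks_match(draws, ref)
})

test_that("deviation-precision conditional is conjugate Gamma", {
  fx <- scalar_fixture()
  st <- fx$state
  a <- fx$hyper$theta_shape_rate["shape"]
  b <- fx$hyper$theta_shape_rate["rate"]
  set.seed(108)
  draws <- chain_of(st, function(s) bhvar:::upd_theta_v(s, fx$hyper),
                    function(s) s$theta_v, n_ks)
  ref <- rgamma(n_ks, a + 0.5, b + st$v[1, 1]^2 / 2)
  expect_ks_match(draws, ref)
})

test_that("L1 prior switch (weight instead of squared weight) still passes", {
  fx <- scalar_fixture()
  hyper <- hyper_params(R = 1, p = 1, gamma_param = "shape_rate",
                        mu1 = 1.2, nu1 = 0.9, mu2 = 1.1, nu2 = 0.8,
                        k_theta = 2, s_theta = 2,
                        K_scale = matrix(1, 1, 1), wishart_dof = 2,
                        l1_prior_on = "lambda1")
  st <- fx$state
  a <- 1.2
  b <- 0.9
  # density of lam1 (not squared): lam1^(a-1) e^(-b lam1) * lam1^2
  #   exp(-lam1^2 u / (2 xi2)); compare on the lam1sq scale
  logf <- function(l1) {
    if (l1 <= 0) return(-Inf)
    (a - 1) * log(l1) - b * l1 + 2 * log(l1) -
      l1^2 * st$two_tau2 / (2 * st$xi2)
  }
  set.seed(109)
  ref_l1 <- sample_logdensity(logf, 1e-8, 25, n_ks)
  draws <- chain_of(st, function(s) bhvar:::upd_lam1(s, hyper),
                    function(s) s$lam1sq, n_ks, thin = 10L)
  expect_ks_match(draws, ref_l1^2)
})

test_that("xi^2 equals the dense Schur-complement definition", {
  expect_equal(compute_xi2(diag(3), 3, 1), rep(1, 9))
  expect_equal(compute_xi2(matrix(4), 1, 1), 0.25)
  set.seed(110)
  for (case in list(c(R = 2, p = 1), c(R = 3, p = 2))) {
    R <- case["R"]; p <- case["p"]
    Lam <- crossprod(matrix(rnorm(R * R), R)) + diag(R)
    M <- kronecker(diag(R * p), solve(Lam))
    K <- R * R * p
    dense <- vapply(seq_len(K), function(k) {
      if (k == K) return(M[K, K])
      tr <- (k + 1):K
      M[k, k] - drop(M[k, tr, drop = FALSE] %*%
                       solve(M[tr, tr, drop = FALSE], M[tr, k]))
    }, numeric(1))
    expect_equal(unname(compute_xi2(Lam, R, p)), unname(dense),
                 tolerance = 1e-10)
    expect_true(all(compute_xi2(Lam, R, p) > 0))
  }
  expect_error(compute_xi2(matrix(c(1, 2, 2, 1), 2), 2, 1),
               "positive definite")
})
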