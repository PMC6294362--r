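# Sampler-level checks: a brute-force grid posterior on the scalar model,
# prior-marginal moment checks, the parameter-expansion identity, the
# ridge limit of the population conditional, and reproducibility contracts.

test_that("scalar-model posterior matches a brute-force grid oracle", {
  # Scalar AR(1), T = 6.  The deviation block is pinned near zero by an
  # extremely concentrated precision hyperprior and the L1/L2 weights by
  # near-degenerate hyperpriors, so the posterior over (w, Lambda, 2tau^2)
  # can be integrated numerically on a grid: p(w, Lambda) ~ likelihood x
  # [ int N(w; 0, 1/(lam2 + 1/u)) Exp(u; rho(Lambda)) du ] x p(Lambda).
  set.seed(42)
  y <- numeric(6)
  y[1] <- rnorm(1)
  for (t in 2:6) y[t] <- 0.7 * y[t - 1] + 0.5 * rnorm(1)

  L1SQ <- 4; L2 <- 1.5
  big_dof <- 4e5
  hyper <- hyper_params(R = 1, p = 1,
                        mu1 = L1SQ, nu1 = big_dof,
                        mu2 = L2, nu2 = big_dof,
                        k_theta = 1e8, s_theta = big_dof,
                        K_scale = matrix(1, 1, 1), wishart_dof = 2)

  # --- independent grid oracle -------------------------------------------
  w_grid <- seq(-1.2, 1.8, length.out = 601)
  lam_grid <- seq(0.02, 60, length.out = 900)
  s_grid <- seq(log(1e-10), log(200), length.out = 800)  # s = log u
  u_grid <- exp(s_grid)
  ds <- s_grid[2] - s_grid[1]
  # N(w; 0, 1/(L2 + 1/u)) over (w, u)
  sd_u <- 1 / sqrt(L2 + 1 / u_grid)
  Wmat <- outer(w_grid, seq_along(u_grid),
                function(w, j) dnorm(w, 0, sd_u[j]))
  # Exp(u; rho) weights over (u, Lambda); xi^2 = 1/Lambda so rho = L1SQ*Lam/2
  rho <- L1SQ * lam_grid / 2
  Umat <- outer(seq_along(u_grid), seq_along(lam_grid), function(i, j) {
    rho[j] * exp(-rho[j] * u_grid[i]) * u_grid[i] * ds  # log-grid Jacobian
  })
  prior_w <- Wmat %*% Umat                                # (w, Lambda)
  h <- y[1:5]
  loglik <- outer(w_grid, lam_grid, function(w, lam) {
    sse <- vapply(w, function(wi) sum((y[2:6] - wi * h)^2), numeric(1))
    2.5 * log(lam) - lam * sse / 2
  })
  post <- exp(loglik - max(loglik)) * prior_w *
    matrix(dgamma(lam_grid, 1, 0.5), nrow = length(w_grid),
           ncol = length(lam_grid), byrow = TRUE)
  pw <- rowSums(post)
  pw <- pw / sum(pw)
  oracle_mean <- sum(w_grid * pw)
  oracle_sd <- sqrt(sum((w_grid - oracle_mean)^2 * pw))

  # --- the sampler -------------------------------------------------------
  panel <- diary_panel(list(patient_series("p01", 1:6, matrix(y))), "y")
  fit <- run_gibbs(panel, p = 1, hyper = hyper, chains = 4,
                   iterations = 3000, warmup = 1000, thin = 2, seed = 77)
  wd <- pool_draws(fit, "w")[, 1]
  expect_equal(mean(wd), oracle_mean, tolerance = 0.05)
  expect_equal(sd(wd), oracle_sd, tolerance = 0.05)
})

test_that("likelihood is identical under expanded and collapsed deviations", {
  sim <- simulate_study_panel(seed = 31, N = 4)
  panel <- preprocess(sim$panel, preprocess_config(log_transform = FALSE))
  fit <- run_gibbs(panel, p = 1, chains = 1, iterations = 60, warmup = 20,
                   thin = 1, seed = 5)
  designs <- build_designs(panel, 1)
  ch <- fit$chains[[1]]
  for (s in c(1, 10, 25, 40)) {
    wn_expanded <- lapply(1:4, function(n) {
      ch$w[s, ] + ch$alpha[s, ] * ch$v[s, n, ]
    })
    wn_collapsed <- lapply(1:4, function(n) ch$w[s, ] + ch$v_star[s, n, ])
    Lam <- ch$Lambda[s, , ]
    expect_equal(var_log_likelihood(designs, wn_expanded, Lam),
                 var_log_likelihood(designs, wn_collapsed, Lam),
                 tolerance = 1e-10)
  }
})

test_that("stronger L2 mass never inflates the population coefficient norm", {
  sim <- simulate_study_panel(seed = 13, N = 6)
  panel <- preprocess(sim$panel, preprocess_config(log_transform = FALSE))
  norms <- vapply(c(1, 1000), function(mu2) {
    hy <- hyper_params(3, 1, mu2 = mu2, nu2 = 50)
    fit <- run_gibbs(panel, p = 1, hyper = hy, chains = 1,
                     iterations = 600, warmup = 300, seed = 99)
    sqrt(sum(colMeans(pool_draws(fit, "w"))^2))
  }, numeric(1))
  expect_lte(norms[2], norms[1])
})

test_that("prior-only sweeps reproduce the prior marginals", {
  # No data: the joint chain must leave the prior invariant, so long-run
  # marginal moments of theta_v match Gamma(2, 2) (mean 1, var 0.5) and
  # Lambda matches its Wishart prior (scalar: mean dof*K = 3, var 6).
  d0 <- list(Y = matrix(0, 1, 0), H = matrix(0, 1, 0), y = numeric(0),
             R = 1L, p = 1L, T_eff = 0L, G = matrix(0, 1, 1),
             C = matrix(0, 1, 1))
  designs <- list(p01 = d0)
  attr(designs, "R") <- 1L
  attr(designs, "p") <- 1L
  attr(designs, "Gsum") <- d0$G
  hyper <- hyper_params(R = 1, p = 1, gamma_param = "shape_rate",
                        mu1 = 1.5, nu1 = 1, mu2 = 1.5, nu2 = 1,
                        k_theta = 2, s_theta = 2,
                        K_scale = matrix(1, 1, 1), wishart_dof = 3)
  set.seed(8)
  state <- init_state(hyper, designs, seed = 8)
  n_it <- 6000
  th <- numeric(n_it)
  lam <- numeric(n_it)
  for (i in seq_len(n_it)) {
    state <- gibbs_sweep(state, designs, hyper)
    th[i] <- state$theta_v
    lam[i] <- drop(state$Lambda)
  }
  keep <- 501:n_it
  expect_equal(mean(th[keep]), 1, tolerance = 0.12)
  expect_equal(var(th[keep]), 0.5, tolerance = 0.25)
  expect_equal(mean(lam[keep]), 3, tolerance = 0.15)
  expect_equal(var(lam[keep]), 6, tolerance = 0.35)
})

test_that("population conditional mean is the generalized ridge solution", {
  # Deviations pinned to zero: the w-conditional mean must equal
  # (sum X' Omega X + D)^-1 sum X' Omega y built densely from first
  # principles (Kronecker design, stacked precision).
  set.seed(21)
  R <- 2; p <- 1
  panel <- toy_panel(N = 3, T_len = 9, R = R, seed = 21)
  designs <- build_designs(panel, p)
  hyper <- hyper_params(R, p)
  state <- init_state(hyper, designs, seed = 3)
  state$v[] <- 0
  state$theta_v[] <- 1e10
  state$Lambda <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  state$two_tau2 <- c(0.5, 1, 2, 0.25)
  state$lam2 <- c(1, 3, 0.5, 2)
  D <- state$lam2 + 1 / state$two_tau2

  P_dense <- diag(D)
  b_dense <- numeric(R * R * p)
  for (d in designs) {
    X <- kronecker(t(d$H), diag(R))
    Om <- kronecker(diag(d$T_eff), state$Lambda)
    P_dense <- P_dense + t(X) %*% Om %*% X
    b_dense <- b_dense + t(X) %*% Om %*% d$y
  }
  ridge <- solve(P_dense, b_dense)
  cw <- bhvar:::cond_w(state, designs)
  expect_equal(drop(solve(cw$P, cw$b)), drop(ridge), tolerance = 1e-8)

  # cross-module limit: D -> 0 on a single patient reproduces the MLE
  one <- designs[1]
  attr(one, "Gsum") <- designs[[1]]$G
  state$lam2[] <- 1e-10
  state$two_tau2[] <- 1e10
  cw0 <- bhvar:::cond_w(state, one)
  mle <- fit_var_mle(panel$patients[[1]]$values, p)
  expect_equal(drop(solve(cw0$P, cw0$b)), mle$w, tolerance = 1e-6)
})

test_that("runs are reproducible and stored draw counts follow the config", {
  sim <- simulate_study_panel(seed = 3, N = 3)
  panel <- preprocess(sim$panel, preprocess_config(log_transform = FALSE))
  fit1 <- run_gibbs(panel, chains = 2, iterations = 80, warmup = 40,
                    thin = 4, seed = 7)
  expect_equal(fit1$config$n_keep, 10)
  expect_equal(dim(fit1$chains[[1]]$w), c(10, 9))
  expect_equal(dim(fit1$chains[[1]]$v_star), c(10, 3, 9))

  fit2 <- run_gibbs(panel, chains = 2, iterations = 80, warmup = 40,
                    thin = 4, seed = 7)
  expect_identical(fit1$chains[[1]]$w, fit2$chains[[1]]$w)
  expect_identical(fit1$chains[[2]]$Lambda, fit2$chains[[2]]$Lambda)

  # equal per-chain seeds give identical chains
  fit3 <- run_gibbs(panel, chains = 2, iterations = 80, warmup = 40,
                    thin = 4, chain_seeds = c(11, 11))
  expect_identical(fit3$chains[[1]]$w, fit3$chains[[2]]$w)
  # different seeds give different hyper draws
  s1 <- init_state(hyper_params(3, 1), build_designs(panel, 1), seed = 1)
  s2 <- init_state(hyper_params(3, 1), build_designs(panel, 1), seed = 2)
  expect_false(any(s1$two_tau2 == s2$two_tau2))
  expect_equal(dim(s1$v), c(3, 9))
  # paper-shaped config arithmetic: (10000 - 5000) / 20 per chain
  expect_equal((10000L - 5000L) %/% 20L, 250L)
})

test_that("draw stores round-trip through disk with verified checksums", {
  sim <- simulate_study_panel(seed = 3, N = 3)
  panel <- preprocess(sim$panel, preprocess_config(log_transform = FALSE))
  fit <- run_gibbs(panel, chains = 2, iterations = 40, warmup = 20, seed = 2)
  dir <- file.path(tempdir(), "drawstore-test")
  write_draws(fit, dir)
  back <- read_draws(dir)
  expect_equal(back$chains[[1]]$w, fit$chains[[1]]$w, tolerance = 1e-12)
  expect_equal(back$chains[[2]]$v_star, fit$chains[[2]]$v_star,
               tolerance = 1e-12)
  expect_equal(back$config$chain_seeds, as.integer(fit$config$chain_seeds))
  # tampering is detected
  wfile <- file.path(dir, "w.csv")
  txt <- readLines(wfile)
  writeLines(c(txt, txt[2]), wfile)
  expect_error(read_draws(dir), "checksum")
  unlink(dir, recursive = TRUE)
})
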