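coef_labels <- function(variable_names, p) {
  R <- length(variable_names)
  labs <- character(0)
  for (i in seq_len(p)) {
    for (cc in seq_len(R)) {
      for (r in seq_len(R)) {
        lab <- paste0(variable_names[cc], "->", variable_names[r])
        if (p > 1) lab <- paste0(lab, ".l", i)
        labs <- c(labs, lab)
      }
    }
  }
  labs
}

#' Fit the hierarchical elastic-net VAR by Gibbs sampling
#'
#' Runs independently seeded chains of [gibbs_sweep()] on a preprocessed
#' panel and stores post-warmup, thinned draws. Stored per draw are the
#' population coefficients `w`, the identified patient deviations
#' `v_star = alpha * v_n` and patient coefficients `w_n = w + v_star`, the
#' expansion vector `alpha`, the innovation precision `Lambda`, and the
#' shrinkage blocks `two_tau2`, `lam1sq`, `lam2`, `theta_v`. The number of
#' stored draws per chain is `(iterations - warmup) / thin`.
#'
#' @param panel a preprocessed [diary_panel] (no missing cells; every
#'   patient longer than `p`).
#' @param p VAR order.
#' @param hyper a [hyper_params()] object (default: [hyper_params()] for
#'   this `R`, `p`).
#' @param chains number of chains (default 4).
#' @param iterations total sweeps per chain (default 2000).
#' @param warmup sweeps discarded (default `iterations / 2`).
#' @param thin keep every `thin`-th post-warmup sweep (default 1).
#' @param seed master seed; per-chain seeds are spawned from it.
#' @param chain_seeds optional explicit per-chain seeds (overrides `seed`
#'   spawning; equal seeds give identical chains).
#' @param verbose print per-chain progress.
#' @return An object of class `bhvar_draws`.
#' @export
run_gibbs <- function(panel, p = 1L, hyper = NULL, chains = 4L,
                      iterations = 2000L, warmup = iterations %/% 2L,
                      thin = 1L, seed = 1L, chain_seeds = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(panel, "diary_panel"))
  R <- length(panel$variable_names)
  if (is.null(hyper)) hyper <- hyper_params(R, p)
  stopifnot(hyper$R == R, hyper$p == p)
  designs <- build_designs(panel, p)
  iterations <- as.integer(iterations)
  warmup <- as.integer(warmup)
  thin <- as.integer(thin)
  stopifnot(iterations > warmup, thin >= 1,
            (iterations - warmup) %% thin == 0)
  n_keep <- (iterations - warmup) %/% thin
  if (is.null(chain_seeds)) {
    set.seed(seed)
    chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  }
  stopifnot(length(chain_seeds) == chains)

  K <- R * R * p
  N <- n_patients(panel)
  chain_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    state <- init_state(hyper, designs, seed = chain_seeds[ch])
    w <- matrix(NA_real_, n_keep, K)
    alpha <- matrix(NA_real_, n_keep, K)
    v_raw <- array(NA_real_, c(n_keep, N, K))
    v_star <- array(NA_real_, c(n_keep, N, K))
    Lambda <- array(NA_real_, c(n_keep, R, R))
    two_tau2 <- matrix(NA_real_, n_keep, K)
    lam1sq <- matrix(NA_real_, n_keep, K)
    lam2 <- matrix(NA_real_, n_keep, K)
    theta_v <- matrix(NA_real_, n_keep, K)
    kept <- 0L
    for (it in seq_len(iterations)) {
      state <- tryCatch(gibbs_sweep(state, designs, hyper),
                        error = function(e) {
                          stop("chain ", ch, ", iteration ", it, ": ",
                               conditionMessage(e))
                        })
      if (it > warmup && (it - warmup) %% thin == 0L) {
        kept <- kept + 1L
        w[kept, ] <- state$w
        alpha[kept, ] <- state$alpha
        v_raw[kept, , ] <- state$v
        v_star[kept, , ] <- sweep(state$v, 2, state$alpha, `*`)
        Lambda[kept, , ] <- state$Lambda
        two_tau2[kept, ] <- state$two_tau2
        lam1sq[kept, ] <- state$lam1sq
        lam2[kept, ] <- state$lam2
        theta_v[kept, ] <- state$theta_v
      }
      if (verbose && it %% max(1L, iterations %/% 10L) == 0L) {
        message("chain ", ch, ": ", it, "/", iterations)
      }
    }
    w_n <- v_star
    for (n in seq_len(N)) w_n[, n, ] <- w_n[, n, ] + w
    chain_list[[ch]] <- list(w = w, alpha = alpha, v = v_raw,
                             v_star = v_star,
                             w_n = w_n, Lambda = Lambda, two_tau2 = two_tau2,
                             lam1sq = lam1sq, lam2 = lam2, theta_v = theta_v,
                             jitter_count = state$jitter_count,
                             lambda_accept_rate =
                               state$lambda_accepts /
                                 max(1L, state$lambda_proposals))
  }
  structure(list(
    chains = chain_list,
    config = list(R = R, p = p, K = K, N = N, chains = chains,
                  iterations = iterations, warmup = warmup, thin = thin,
                  n_keep = n_keep, seed = seed, chain_seeds = chain_seeds,
                  patient_ids = names(panel$patients),
                  variable_names = panel$variable_names,
                  coef_names = coef_labels(panel$variable_names, p)),
    hyper = hyper), class = "bhvar_draws")
}

#' @export
print.bhvar_draws <- function(x, ...) {
  cfg <- x$config
  cat("bhvar_draws: ", cfg$chains, " chain(s) x ", cfg$n_keep,
      " stored draws (", cfg$iterations, " iterations, warmup ",
      cfg$warmup, ", thin ", cfg$thin, ")\n", sep = "")
  cat("  model: R = ", cfg$R, ", p = ", cfg$p, ", N = ", cfg$N,
      " patients, K = ", cfg$K, " coefficients\n", sep = "")
  ar <- mean(vapply(x$chains, `[[`, numeric(1), "lambda_accept_rate"))
  cat("  Lambda MH acceptance rate: ", round(ar, 3), "\n", sep = "")
  invisible(x)
}

#' Pool stored draws across chains
#'
#' @param draws a `bhvar_draws` object.
#' @param field one of `"w"`, `"alpha"`, `"v"` (raw, unidentified
#'   deviations), `"v_star"`, `"w_n"`, `"Lambda"`, `"two_tau2"`,
#'   `"lam1sq"`, `"lam2"`, `"theta_v"`.
#' @return A matrix (draws x K) or array (draws x N x K, draws x R x R)
#'   with all chains stacked.
#' @export
pool_draws <- function(draws, field = "w") {
  xs <- lapply(draws$chains, `[[`, field)
  if (length(dim(xs[[1]])) == 2) {
    do.call(rbind, xs)
  } else {
    d <- dim(xs[[1]])
    out <- array(NA_real_, c(sum(vapply(xs, function(a) dim(a)[1], 0)),
                             d[2], d[3]))
    at <- 0L
    for (a in xs) {
      out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
}

#' Per-chain draw matrices for one field
#'
#' Flattens each chain's draws for `field` into a (draws x parameters)
#' matrix; used by the convergence diagnostics.
#'
#' @inheritParams pool_draws
#' @return A list with one matrix per chain.
#' @export
chain_matrices <- function(draws, field = "w") {
  lapply(draws$chains, function(chn) {
    x <- chn[[field]]
    if (length(dim(x)) == 2) x else matrix(x, nrow = dim(x)[1])
  })
}

#' Plug-in AIC of the hierarchical fit
#'
#' Evaluates the VAR log likelihood at the posterior-mode patient
#' coefficients and posterior-mode innovation precision, with parameter
#' count [hier_param_count()]. If the element-wise mode of `Lambda` is not
#' positive definite, the posterior mean is used instead.
#'
#' @param draws a `bhvar_draws` object.
#' @param panel the preprocessed training [diary_panel].
#' @return A list with `aic`, `loglik`, `n_params`.
#' @export
hier_aic <- function(draws, panel) {
  cfg <- draws$config
  designs <- build_designs(panel, cfg$p)
  wn <- pool_draws(draws, "w_n")
  modes <- apply(wn, c(2, 3), empirical_mode)
  Lam_draws <- pool_draws(draws, "Lambda")
  Lam <- apply(Lam_draws, c(2, 3), empirical_mode)
  Lam <- (Lam + t(Lam)) / 2
  if (min(eigen(Lam, only.values = TRUE)$values) <= 0) {
    Lam <- apply(Lam_draws, c(2, 3), mean)
  }
  ll <- var_log_likelihood(designs, modes, Lam)
  np <- hier_param_count(cfg$R, cfg$p, cfg$N)
  list(aic = aic(ll, np), loglik = ll, n_params = np)
}

#' Select a VAR order by AIC
#'
#' Fits the hierarchical model at each candidate order and returns the
#' order with the smallest plug-in AIC.
#'
#' @param panel preprocessed [diary_panel].
#' @param orders candidate orders (default `1:2`).
#' @param ... passed to [run_gibbs()].
#' @return A list with `order` (the selected order) and `aic` (named
#'   vector of AIC values).
#' @export
select_order <- function(panel, orders = 1:2, ...) {
  aics <- vapply(orders, function(p) {
    fit <- run_gibbs(panel, p = p, ...)
    hier_aic(fit, panel)$aic
  }, numeric(1))
  names(aics) <- paste0("p", orders)
  list(order = orders[which.min(aics)], aic = aics)
}
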