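#' Draw ground-truth parameters for a synthetic hierarchical VAR panel
#'
#' Samples a sparse population coefficient vector and per-patient deviations
#' from the hierarchical VAR generative model, enforcing stationarity of
#' every patient's implied VAR (companion spectral radius < 1, redrawing a
#' patient's deviation up to `max_tries` times).
#'
#' @param R number of variables.
#' @param p VAR order.
#' @param N number of patients.
#' @param sparsity fraction of exactly-zero entries in the population vector
#'   (in `[0, 1]`); nonzero entries are drawn `Uniform(+/-[0.1, 0.6])`.
#' @param hetero_sd per-coefficient standard deviation of the patient
#'   deviations; scalar or length `R^2 p`.
#' @param Lambda_true innovation precision matrix (default identity).
#' @param trend_slopes optional `N x R` matrix of linear trend slopes added
#'   after simulation (default none).
#' @param missing_rate fraction of cells set missing completely at random by
#'   [simulate_panel()] (in `[0, 1)`).
#' @param seed RNG seed (integer).
#' @param max_tries redraw attempts per patient for the stationarity guard.
#' @return An object of class `synthetic_truth` with fields `w_true`
#'   (length `R^2 p`), `v_true` (`N x R^2 p`), `Lambda_true`, `hetero_sd`,
#'   `trend_slopes`, `missing_rate`, `R`, `p`, `N`, `seed`.
#' @export
sample_truth <- function(R, p, N, sparsity = 0.5, hetero_sd = 0.2,
                         Lambda_true = diag(R), trend_slopes = NULL,
                         missing_rate = 0, seed = 1L, max_tries = 100L) {
  stopifnot(sparsity >= 0, sparsity <= 1, missing_rate >= 0, missing_rate < 1)
  K <- R * R * p
  hetero_sd <- rep_len(hetero_sd, K)
  set.seed(seed)
  draw_w <- function() {
    w <- numeric(K)
    nz <- stats::runif(K) >= sparsity
    w[nz] <- sample(c(-1, 1), sum(nz), replace = TRUE) *
      stats::runif(sum(nz), 0.1, 0.6)
    w
  }
  w_true <- NULL
  for (try in seq_len(max_tries)) {
    cand <- draw_w()
    if (companion_spectral_radius(coef_to_matrices(cand, R, p)) < 1) {
      w_true <- cand
      break
    }
  }
  if (is.null(w_true)) {
    stop("could not draw a stationary population matrix in ", max_tries,
         " attempts; reduce magnitudes or sparsity")
  }
  v_true <- matrix(0, N, K)
  for (n in seq_len(N)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      v <- stats::rnorm(K, 0, hetero_sd)
      if (companion_spectral_radius(coef_to_matrices(w_true + v, R, p)) < 1) {
        v_true[n, ] <- v
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not draw a stationary patient matrix in ", max_tries,
           " attempts; reduce hetero_sd or coefficient magnitudes")
    }
  }
  structure(list(w_true = w_true, v_true = v_true, Lambda_true = Lambda_true,
                 hetero_sd = hetero_sd, trend_slopes = trend_slopes,
                 missing_rate = missing_rate, R = R, p = p, N = N,
                 seed = seed),
            class = "synthetic_truth")
}

#' Simulate a diary panel from ground-truth parameters
#'
#' Iterates the VAR recursion per patient from zero initial lags with
#' innovations `MVN(0, solve(Lambda_true))`, discards `burn_in` steps,
#' optionally adds per-patient linear trends and finally masks cells
#' missing completely at random at `truth$missing_rate`.
#'
#' @param truth a [sample_truth()] object.
#' @param T_n per-patient series lengths (scalar or length `N`).
#' @param burn_in steps discarded before the retained series (default 200).
#' @param seed RNG seed for innovations and missingness.
#' @param variable_names labels for the `R` variables.
#' @param init_lags optional `p x R` matrix of starting lag values (newest
#'   first); defaults to zeros, which is why a burn-in is used.
#' @return A [diary_panel] with patients `"p01", "p02", ...`.
#' @export
simulate_panel <- function(truth, T_n, burn_in = 200L, seed = 1L,
                           variable_names = paste0("V", seq_len(truth$R)),
                           init_lags = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  R <- truth$R
  p <- truth$p
  N <- truth$N
  T_n <- rep_len(as.integer(T_n), N)
  stopifnot(all(T_n > p))
  set.seed(seed)
  Sigma <- solve(truth$Lambda_true)
  Lchol <- chol(Sigma)
  ids <- sprintf("p%02d", seq_len(N))
  patients <- vector("list", N)
  for (n in seq_len(N)) {
    A <- matrix(truth$w_true + truth$v_true[n, ], nrow = R)   # R x Rp
    total <- burn_in + T_n[n]
    ymat <- matrix(0, total + p, R)                            # zero initial lags
    if (!is.null(init_lags)) ymat[p:1, ] <- init_lags
    eps <- matrix(stats::rnorm(total * R), total, R) %*% Lchol
    for (t in seq_len(total)) {
      lags <- as.vector(t(ymat[(t + p - 1):t, , drop = FALSE]))
      ymat[t + p, ] <- A %*% lags + eps[t, ]
    }
    vals <- ymat[(p + burn_in + 1):(p + total), , drop = FALSE]
    if (!is.null(truth$trend_slopes)) {
      vals <- vals + outer(seq_len(T_n[n]), truth$trend_slopes[n, ])
    }
    colnames(vals) <- variable_names
    mask <- matrix(stats::runif(length(vals)) < truth$missing_rate,
                   nrow(vals), ncol(vals))
    vals[mask] <- NA_real_
    patients[[n]] <- patient_series(ids[n], seq_len(T_n[n]), vals,
                                    missing_mask = mask)
  }
  diary_panel(patients, variable_names)
}

#' Simulate an Application-style diary panel
#'
#' Convenience wrapper producing a panel shaped like a 25-patient, 3-variable
#' daily diary study: series lengths drawn around 25.5 days (clamped to
#' 10-33), sparse population dynamics, moderate between-patient
#' heterogeneity, identity innovation precision and ~3% missing days.
#'
#' @param seed RNG seed.
#' @param N,R,p panel shape (defaults 25, 3, 1).
#' @param sparsity,hetero_sd generative-model settings (defaults 0.5, 0.2).
#' @param missing_rate fraction of missing cells (default 0.03).
#' @return A list with `truth` (the [sample_truth()] object) and `panel`
#'   (the simulated [diary_panel], variables `tobacco`, `negaff`, `craving`).
#' @export
simulate_study_panel <- function(seed = 1L, N = 25L, R = 3L, p = 1L,
                                 sparsity = 0.5, hetero_sd = 0.2,
                                 missing_rate = 0.03) {
  truth <- sample_truth(R = R, p = p, N = N, sparsity = sparsity,
                        hetero_sd = hetero_sd, missing_rate = missing_rate,
                        seed = seed)
  set.seed(seed + 1L)
  T_n <- pmin(33L, pmax(10L, as.integer(round(stats::rnorm(N, 25.5, 5)))))
  nm <- if (R == 3) c("tobacco", "negaff", "craving")
        else paste0("V", seq_len(R))
  panel <- simulate_panel(truth, T_n, seed = seed + 2L, variable_names = nm)
  list(truth = truth, panel = panel)
}
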