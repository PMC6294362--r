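#' Split a panel into training and held-out test days
#'
#' Splits by position within each patient's (preprocessed) series: the last
#' `n_test` days of every patient form the test set. Both the one-day
#' holdout and the ten-day holdout protocols are positions of this split.
#'
#' @param panel a [diary_panel].
#' @param n_test number of held-out days per patient (default 1).
#' @return A list with `train` and `test` panels (the test panel keeps the
#'   original day indices).
#' @export
holdout_split <- function(panel, n_test = 1L) {
  n_test <- as.integer(n_test)
  stopifnot(n_test >= 1)
  tr <- list()
  te <- list()
  for (ps in panel$patients) {
    T_len <- nrow(ps$values)
    stopifnot(T_len > n_test)
    keep <- seq_len(T_len - n_test)
    hold <- (T_len - n_test + 1):T_len
    tr[[ps$patient_id]] <- patient_series(ps$patient_id, ps$days[keep],
                                          ps$values[keep, , drop = FALSE],
                                          ps$missing_mask[keep, , drop = FALSE])
    te[[ps$patient_id]] <- patient_series(ps$patient_id, ps$days[hold],
                                          ps$values[hold, , drop = FALSE],
                                          ps$missing_mask[hold, , drop = FALSE],
                                          fill_gaps = FALSE)
  }
  list(train = diary_panel(tr, panel$variable_names, panel$meta),
       test = diary_panel(te, panel$variable_names, panel$meta))
}

forecast_frame <- function(patient_ids, H, variable_names, point, lo, hi) {
  grid <- expand.grid(variable = variable_names, h = seq_len(H),
                      patient_id = patient_ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("patient_id", "h", "variable")]
  grid$point <- point
  grid$lo <- lo
  grid$hi <- hi
  class(grid) <- c("bhvar_forecast", "data.frame")
  grid
}

#' Posterior-predictive recursive forecasts
#'
#' For every stored posterior draw and patient, builds the patient's lag
#' matrices from `w + v_star`, draws one innovation per step from
#' `MVN(0, solve(Lambda))` with that draw's precision, and iterates the VAR
#' recursion for `h = 1..H`, feeding forecasts back as lags. Point
#' forecasts are the means of the predictive draws; intervals are the
#' 2.5th and 97.5th predictive percentiles.
#'
#' @param draws a `bhvar_draws` object.
#' @param panel the training [diary_panel] the draws were fitted to (its
#'   last `p` days per patient seed the recursion).
#' @param H forecast horizon (>= 1).
#' @param seed RNG seed for the predictive innovations.
#' @param keep_draws retain the predictive draw array (draws x N x H x R).
#' @return A `bhvar_forecast` data.frame with columns `patient_id`, `h`,
#'   `variable`, `point`, `lo`, `hi`; the draw array is attached as
#'   `attr(x, "draws")` when `keep_draws = TRUE`.
#' @export
posterior_forecast <- function(draws, panel, H = 1L, seed = 1L,
                               keep_draws = FALSE) {
  H <- as.integer(H)
  if (H < 1) stop("horizon must be >= 1")
  cfg <- draws$config
  R <- cfg$R
  p <- cfg$p
  N <- cfg$N
  stopifnot(identical(names(panel$patients), cfg$patient_ids))
  wn <- pool_draws(draws, "w_n")
  Lam <- pool_draws(draws, "Lambda")
  S <- dim(wn)[1]
  set.seed(seed)
  pred <- array(NA_real_, c(S, N, H, R))
  for (n in seq_len(N)) {
    ps <- panel$patients[[n]]
    T_len <- nrow(ps$values)
    stopifnot(T_len >= p)
    init_lags <- ps$values[T_len:(T_len - p + 1), , drop = FALSE]  # lag1 first
    for (s in seq_len(S)) {
      A <- matrix(wn[s, n, ], nrow = R)
      Sig <- solve(Lam[s, , ])
      ch <- chol((Sig + t(Sig)) / 2)
      lags <- init_lags                                   # p x R, lag 1 first row
      for (h in seq_len(H)) {
        eps <- drop(crossprod(ch, stats::rnorm(R)))
        yhat <- drop(A %*% as.vector(t(lags))) + eps
        pred[s, n, h, ] <- yhat
        if (p == 1) {
          lags[1, ] <- yhat
        } else {
          lags <- rbind(yhat, lags[-p, , drop = FALSE])
        }
      }
    }
  }
  shp <- dim(pred)[2:4]
  point <- array(apply(pred, c(2, 3, 4), mean), shp)
  qs <- apply(pred, c(2, 3, 4), stats::quantile, probs = c(0.025, 0.975),
              type = 7, names = FALSE)
  lo <- array(qs[1, , , ], shp)
  hi <- array(qs[2, , , ], shp)
  out <- forecast_frame(cfg$patient_ids, H, cfg$variable_names,
                        point = as.vector(aperm(point, c(3, 2, 1))),
                        lo = as.vector(aperm(lo, c(3, 2, 1))),
                        hi = as.vector(aperm(hi, c(3, 2, 1))))
  if (keep_draws) attr(out, "draws") <- pred
  out
}

#' Evaluate forecasts against held-out data
#'
#' MSE per variable is the mean squared point-forecast error over patients
#' and horizons; the overall MSE is the mean of the per-variable MSEs.
#' Coverage is the fraction of (patient, horizon, variable) cells whose
#' truth lies inside the interval. When a comparator forecast is given,
#' `width_narrower` is the fraction of cells whose interval is strictly
#' narrower than the comparator's.
#'
#' @param forecasts a `bhvar_forecast` data.frame.
#' @param truth the held-out test [diary_panel]; its `h`-th row per patient
#'   is matched to horizon `h`. Cells missing in the truth are dropped.
#' @param comparator optional second `bhvar_forecast` on the same cells.
#' @return A list with `mse_overall`, `mse_by_variable`, `coverage`,
#'   `width_narrower` (NA without a comparator), and `n_cells`.
#' @export
evaluate_forecasts <- function(forecasts, truth, comparator = NULL) {
  truth_df <- do.call(rbind, lapply(truth$patients, function(ps) {
    data.frame(patient_id = ps$patient_id, h = seq_len(nrow(ps$values)),
               variable = rep(truth$variable_names, each = nrow(ps$values)),
               actual = as.vector(ps$values), stringsAsFactors = FALSE)
  }))
  truth_df <- truth_df[!is.na(truth_df$actual), , drop = FALSE]
  m <- merge(as.data.frame(forecasts), truth_df,
             by = c("patient_id", "h", "variable"))
  if (nrow(m) < nrow(truth_df)) {
    miss <- merge(truth_df, as.data.frame(forecasts),
                  by = c("patient_id", "h", "variable"), all.x = TRUE)
    miss <- miss[is.na(miss$point), c("patient_id", "h", "variable")]
    stop("forecast cells missing for: ",
         paste(utils::head(apply(miss, 1, paste, collapse = "/"), 5),
               collapse = ", "))
  }
  err2 <- (m$point - m$actual)^2
  mse_by_var <- tapply(err2, m$variable, mean)
  mse_by_var <- stats::setNames(as.numeric(mse_by_var[truth$variable_names]),
                                truth$variable_names)
  coverage <- mean(m$actual >= m$lo & m$actual <= m$hi)
  width_narrower <- NA_real_
  if (!is.null(comparator)) {
    comp <- as.data.frame(comparator)
    names(comp)[names(comp) %in% c("point", "lo", "hi")] <-
      c("point_c", "lo_c", "hi_c")
    mc <- merge(m, comp, by = c("patient_id", "h", "variable"))
    if (nrow(mc) != nrow(m)) stop("comparator cells do not align")
    width_narrower <- mean((mc$hi - mc$lo) < (mc$hi_c - mc$lo_c))
  }
  list(mse_overall = mean(mse_by_var),
       mse_by_variable = mse_by_var,
       coverage = coverage,
       width_narrower = width_narrower,
       n_cells = nrow(m))
}
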