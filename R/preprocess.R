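#' Preprocessing configuration for diary panels
#'
#' Encodes the per-patient, per-variable preprocessing pipeline applied before
#' model fitting: imputation of missing days, an optional log transform,
#' standardization to sample mean 0 / variance 1, and removal of a linear
#' day trend by OLS residualisation.
#'
#' @param imputation `"flank_mean"` (mean of the nearest non-missing values on
#'   either side of a missing run; boundary runs copy the single nearest
#'   value) or `"moving_average"` (centered window mean of available values,
#'   window widened at the boundaries).
#' @param ma_window positive integer window half-width basis for
#'   `"moving_average"` (total span `2 * ma_window + 1` before widening);
#'   default 4.
#' @param log_transform apply `log(x + log_offset)`; default `TRUE`.
#' @param log_offset nonnegative shift before the log; default 0. Use 1 for
#'   count-like scales that include 0 (e.g. cigarettes on a 0-5 scale).
#' @param standardize center/scale each series to sample mean 0, variance 1
#'   (denominator `T - 1`); default `TRUE`.
#' @param detrend replace each series by the residuals of OLS on
#'   `(1, day)`; default `TRUE`.
#' @param standardize_before_detrend order of the last two steps; default
#'   `TRUE` (standardize, then detrend). The applied order is recorded in the
#'   panel's provenance attribute.
#' @param daily_average collapse repeated days before anything else.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(imputation = c("flank_mean", "moving_average"),
                              ma_window = 4L,
                              log_transform = TRUE, log_offset = 0,
                              standardize = TRUE, detrend = TRUE,
                              standardize_before_detrend = TRUE,
                              daily_average = FALSE) {
  imputation <- match.arg(imputation)
  ma_window <- as.integer(ma_window)
  stopifnot(ma_window >= 1L, log_offset >= 0)
  structure(list(imputation = imputation, ma_window = ma_window,
                 log_transform = isTRUE(log_transform),
                 log_offset = log_offset,
                 standardize = isTRUE(standardize), detrend = isTRUE(detrend),
                 standardize_before_detrend = isTRUE(standardize_before_detrend),
                 daily_average = isTRUE(daily_average)),
            class = "preprocess_config")
}

#' Impute missing entries of a single series
#'
#' `flank_mean` fills every missing run with the mean of the nearest
#' non-missing value before and after the run; a run touching the boundary
#' copies the single nearest non-missing value. `moving_average` replaces each
#' missing entry by the mean of available values in a centered window,
#' widening the window until at least one observed value is captured.
#'
#' @param x numeric vector with `NA` for missing entries.
#' @param method `"flank_mean"` or `"moving_average"`.
#' @param window integer half-width for `"moving_average"` (default 4).
#' @return A complete numeric vector of the same length.
#' @export
impute_series <- function(x, method = c("flank_mean", "moving_average"),
                          window = 4L) {
  method <- match.arg(method)
  if (all(is.na(x))) stop("cannot impute an all-missing series")
  if (!anyNA(x)) return(x)
  n <- length(x)
  obs <- which(!is.na(x))
  if (method == "flank_mean") {
    out <- x
    for (i in which(is.na(x))) {
      before <- obs[obs < i]
      after <- obs[obs > i]
      left <- if (length(before)) x[max(before)] else NA_real_
      right <- if (length(after)) x[min(after)] else NA_real_
      out[i] <- mean(c(left, right), na.rm = TRUE)
    }
    out
  } else {
    out <- x
    for (i in which(is.na(x))) {
      w <- as.integer(window)
      repeat {
        lo <- max(1L, i - w)
        hi <- min(n, i + w)
        vals <- x[lo:hi]
        if (any(!is.na(vals))) break
        w <- w + 1L
      }
      out[i] <- mean(vals, na.rm = TRUE)
    }
    out
  }
}

standardize_series <- function(x, patient_id, variable) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    stop("zero variance series for patient '", patient_id, "', variable '",
         variable, "': cannot standardize")
  }
  (x - mean(x)) / s
}

detrend_series <- function(x, days) {
  stats::lm.fit(cbind(1, days), x)$residuals
}

#' Preprocess a diary panel for VAR modelling
#'
#' Applies, per patient and per variable: (optional) daily averaging,
#' imputation, `log(x + offset)`, standardization to sample mean 0 and
#' variance 1, and linear detrending against the day index (OLS residuals).
#' The order of the last two steps follows
#' `cfg$standardize_before_detrend`. A provenance record of the applied
#' steps is attached as `attr(panel, "provenance")`.
#'
#' @param panel a [diary_panel].
#' @param cfg a [preprocess_config].
#' @return A preprocessed [diary_panel] with no missing entries.
#' @export
preprocess <- function(panel, cfg = preprocess_config()) {
  stopifnot(inherits(panel, "diary_panel"), inherits(cfg, "preprocess_config"))
  if (cfg$daily_average) panel <- daily_average(panel)
  steps <- c("impute",
             if (cfg$log_transform) "log",
             if (cfg$standardize_before_detrend) {
               c(if (cfg$standardize) "standardize", if (cfg$detrend) "detrend")
             } else {
               c(if (cfg$detrend) "detrend", if (cfg$standardize) "standardize")
             })
  patients <- lapply(panel$patients, function(ps) {
    v <- ps$values
    for (r in seq_len(ncol(v))) {
      x <- v[, r]
      for (step in steps) {
        x <- switch(step,
          impute = impute_series(x, cfg$imputation, cfg$ma_window),
          log = {
            shifted <- x + cfg$log_offset
            if (any(shifted <= 0)) {
              stop("non-positive value before log for patient '",
                   ps$patient_id, "', variable '", panel$variable_names[r],
                   "'; raise log_offset")
            }
            log(shifted)
          },
          standardize = standardize_series(x, ps$patient_id,
                                           panel$variable_names[r]),
          detrend = detrend_series(x, ps$days))
      }
      v[, r] <- x
    }
    patient_series(ps$patient_id, ps$days, v,
                   missing_mask = matrix(FALSE, nrow(v), ncol(v)))
  })
  out <- diary_panel(patients, panel$variable_names, panel$meta)
  attr(out, "provenance") <- list(steps = steps, config = unclass(cfg))
  out
}
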