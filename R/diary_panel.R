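#' Construct a patient diary series
#'
#' A `patient_series` holds one patient's day-indexed multivariate diary
#' measurements: a strictly increasing 1-based integer day index, a
#' `T x R` value matrix and a logical missingness mask of the same shape.
#' Gaps in the day index are materialised as fully-missing rows so that
#' downstream lag structure is aligned to calendar days.
#'
#' @param patient_id character scalar identifying the patient.
#' @param days integer vector of day indices (strictly increasing, >= 1).
#' @param values numeric matrix, one row per day, one column per variable.
#' @param missing_mask logical matrix, same shape as `values`; `TRUE` marks
#'   a missing cell. Defaults to `is.na(values)`.
#' @param fill_gaps if `TRUE` (default), days absent from `days` between
#'   `min(days)` and `max(days)` are inserted as all-missing rows.
#' @param allow_duplicates permit repeated day indices (raw multi-record-per-day
#'   data, prior to [daily_average()]); implies `fill_gaps = FALSE`.
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, days, values, missing_mask = NULL,
                           fill_gaps = TRUE, allow_duplicates = FALSE) {
  values <- as.matrix(values)
  days <- as.integer(days)
  if (anyDuplicated(days)) {
    if (!allow_duplicates) {
      stop("duplicate day indices for patient '", patient_id, "': ",
           paste(unique(days[duplicated(days)]), collapse = ", "))
    }
    fill_gaps <- FALSE
  }
  if (is.unsorted(days, strictly = !allow_duplicates)) {
    ord <- order(days)
    days <- days[ord]
    values <- values[ord, , drop = FALSE]
    if (!is.null(missing_mask)) missing_mask <- missing_mask[ord, , drop = FALSE]
  }
  if (any(days < 1L)) stop("day indices must be >= 1")
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  stopifnot(identical(dim(values), dim(missing_mask)))
  if (any(!missing_mask & !is.finite(values))) {
    stop("non-finite value in a cell not flagged missing for patient '",
         patient_id, "'")
  }
  if (fill_gaps && length(days) > 0) {
    full <- seq.int(days[1L], days[length(days)])
    if (length(full) > length(days)) {
      R <- ncol(values)
      v <- matrix(NA_real_, length(full), R, dimnames = list(NULL, colnames(values)))
      m <- matrix(TRUE, length(full), R)
      idx <- match(days, full)
      v[idx, ] <- values
      m[idx, ] <- missing_mask
      days <- full
      values <- v
      missing_mask <- m
    }
  }
  values[missing_mask] <- NA_real_
  structure(list(patient_id = as.character(patient_id), days = days,
                 values = values, missing_mask = missing_mask),
            class = "patient_series")
}

#' Construct a diary panel
#'
#' A `diary_panel` is the container for a multi-patient diary study: a list
#' of [patient_series] sharing the same `R` variables, plus optional
#' per-patient demographics (e.g. gender, age) used by the group summaries.
#'
#' @param patients list of [patient_series] objects.
#' @param variable_names character vector of the `R` variable labels.
#' @param meta optional `data.frame` with a `patient_id` column and
#'   demographic columns.
#' @return An object of class `diary_panel`.
#' @export
diary_panel <- function(patients, variable_names, meta = NULL) {
  stopifnot(length(patients) >= 1, length(variable_names) >= 1)
  for (ps in patients) {
    stopifnot(inherits(ps, "patient_series"))
    if (ncol(ps$values) != length(variable_names)) {
      stop("patient '", ps$patient_id, "' has ", ncol(ps$values),
           " variables; panel declares ", length(variable_names))
    }
  }
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in panel")
  names(patients) <- ids
  if (!is.null(meta)) {
    stopifnot(is.data.frame(meta), "patient_id" %in% names(meta))
    meta$patient_id <- as.character(meta$patient_id)
  }
  structure(list(patients = patients, variable_names = as.character(variable_names),
                 meta = meta),
            class = "diary_panel")
}

#' @export
print.diary_panel <- function(x, ...) {
  Tn <- vapply(x$patients, function(p) nrow(p$values), integer(1))
  cat("diary_panel: ", length(x$patients), " patients, ",
      length(x$variable_names), " variables (",
      paste(x$variable_names, collapse = ", "), ")\n", sep = "")
  cat("  days per patient: min ", min(Tn), ", median ", stats::median(Tn),
      ", max ", max(Tn), "\n", sep = "")
  nmiss <- sum(vapply(x$patients, function(p) sum(p$missing_mask), integer(1)))
  cat("  missing cells: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' Number of patients in a panel
#' @param panel a [diary_panel].
#' @return integer.
#' @export
n_patients <- function(panel) length(panel$patients)

#' Read a long-format diary CSV into a panel
#'
#' Expects one row per (patient, day) observation with a patient-id column, a
#' day column and one column per diary variable. Blank or `NA` cells become
#' missing-mask entries. Multiple rows for the same (patient, day) are an
#' error unless `daily_average = TRUE`, in which case they are averaged by
#' [daily_average()].
#'
#' @param path CSV file path.
#' @param schema named list mapping roles to column names:
#'   `patient_id`, `day`, `variables` (character vector), and optionally
#'   `demographics` (character vector, e.g. `c("gender", "age")`).
#' @param daily_average collapse repeated days by averaging (default `FALSE`).
#' @return A [diary_panel].
#' @export
read_panel_csv <- function(path, schema, daily_average = FALSE) {
  stopifnot(file.exists(path))
  stopifnot(all(c("patient_id", "day", "variables") %in% names(schema)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0) stop("no records in '", path, "'")
  need <- c(schema$patient_id, schema$day, schema$variables, schema$demographics)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns in '", path, "': ",
                         paste(miss, collapse = ", "))

  pid <- df[[schema$patient_id]]
  day <- suppressWarnings(as.integer(df[[schema$day]]))
  if (anyNA(day)) stop("non-integer day value at row(s) ",
                       paste(which(is.na(day)), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(schema$variables),
                 dimnames = list(NULL, schema$variables))
  for (v in schema$variables) {
    raw <- trimws(df[[v]])
    blank <- is.na(raw) | raw == "" | toupper(raw) == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(num))
    if (length(bad)) stop("non-numeric value in column '", v, "' at row(s) ",
                          paste(bad, collapse = ", "))
    num[blank] <- NA_real_
    vals[, v] <- num
  }

  key <- paste(pid, day, sep = "\r")
  if (!daily_average && anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (patient, day) rows: ",
         paste(gsub("\r", " day ", utils::head(dup, 5)), collapse = "; "),
         if (length(dup) > 5) " ..." else "")
  }

  patients <- lapply(split(seq_len(nrow(df)), pid), function(idx) {
    d <- day[idx]
    v <- vals[idx, , drop = FALSE]
    if (daily_average && anyDuplicated(d)) {
      agg <- lapply(split(seq_along(d), d), function(j) {
        colMeans(v[j, , drop = FALSE], na.rm = TRUE)
      })
      d2 <- as.integer(names(agg))
      v <- do.call(rbind, agg)
      rownames(v) <- NULL
      v[is.nan(v)] <- NA_real_
      d <- d2
    }
    patient_series(pid[idx[1]], d, v)
  })
  patients <- patients[order(names(patients))]

  meta <- NULL
  if (!is.null(schema$demographics)) {
    mrows <- !duplicated(pid)
    meta <- data.frame(patient_id = pid[mrows], df[mrows, schema$demographics,
                                                   drop = FALSE],
                       stringsAsFactors = FALSE, check.names = FALSE)
    for (col in schema$demographics) {
      num <- suppressWarnings(as.numeric(meta[[col]]))
      if (!anyNA(num)) meta[[col]] <- num
    }
    meta <- meta[order(meta$patient_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  diary_panel(patients, schema$variables, meta)
}

#' Write a panel back to the long-format CSV dialect
#'
#' Emits the same dialect [read_panel_csv()] consumes: columns
#' `patient_id, day, <variables...>` plus any demographic columns in
#' `panel$meta`. Missing cells are written as empty fields.
#'
#' @param panel a [diary_panel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  rows <- lapply(panel$patients, function(ps) {
    v <- ps$values
    v[ps$missing_mask] <- NA_real_
    data.frame(patient_id = ps$patient_id, day = ps$days, v,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("patient_id", "day", panel$variable_names)
  if (!is.null(panel$meta)) {
    df <- merge(df, panel$meta, by = "patient_id", sort = FALSE)
  }
  df <- df[order(df$patient_id, df$day), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Collapse multiple same-day records to daily means
#'
#' Ensures one observation per (patient, day) by averaging the non-missing
#' entries of each variable within the day. A day whose entries are all
#' missing for a variable stays missing for that variable.
#'
#' @param panel a [diary_panel].
#' @return A [diary_panel] with unique day indices per patient.
#' @export
daily_average <- function(panel) {
  patients <- lapply(panel$patients, function(ps) {
    if (!anyDuplicated(ps$days)) return(ps)
    agg <- lapply(split(seq_along(ps$days), ps$days), function(j) {
      m <- colMeans(ps$values[j, , drop = FALSE], na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      m
    })
    v <- do.call(rbind, agg)
    rownames(v) <- NULL
    patient_series(ps$patient_id, as.integer(names(agg)), v)
  })
  diary_panel(patients, panel$variable_names, panel$meta)
}
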