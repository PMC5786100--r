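# Drift-time -> CCS calibration on polyalanine standards.
#
# Traveling-wave drift times are converted to CCS through an ordinary
# least-squares line fitted on calibrant ions of known CCS; the same line
# is then applied to analyte drift times.  Internal values keep full
# precision; rounding to the integer angstrom^2 of published tables is a
# rendering choice.

#' Assemble a calibrant series
#'
#' @param species character ids (e.g. polyalanine chain lengths).
#' @param mz mass-to-charge ratios (optional bookkeeping, may be `NA`).
#' @param drift_time drift times in ms, strictly positive.
#' @param reference_ccs known CCS in angstrom^2.
#' @return data frame of class `calibrant_series`.
#' @export
calibrant_series <- function(species, drift_time, reference_ccs, mz = NA) {
  out <- data.frame(
    species = as.character(species),
    mz = mz,
    drift_time = as.numeric(drift_time),
    reference_ccs = as.numeric(reference_ccs)
  )
  if (nrow(out) < 2) stop("calibration needs at least two calibrant points")
  if (any(out$drift_time <= 0)) stop("drift times must be strictly positive")
  if (length(unique(out$drift_time)) == 1) {
    stop("all drift times identical: calibration line is singular")
  }
  class(out) <- c("calibrant_series", "data.frame")
  out
}

#' Read a calibrant or analyte table
#'
#' Delimited text with a header; calibrant tables carry columns
#' `species, mz, drift_ms, ccs_A2`, analyte tables `species, mz, drift_ms`.
#'
#' @param path file path.
#' @return `calibrant_series` when a `ccs_A2` column is present, otherwise
#'   a plain data frame of analytes.
#' @export
read_calibrant_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", strip.white = TRUE)
  if (!all(c("species", "drift_ms") %in% names(tab))) {
    stop("table needs at least columns species, drift_ms")
  }
  if ("ccs_A2" %in% names(tab)) {
    calibrant_series(tab$species, tab$drift_ms, tab$ccs_A2,
      mz = if ("mz" %in% names(tab)) tab$mz else NA
    )
  } else {
    tab
  }
}

#' Fit the linear drift-time -> CCS calibration
#'
#' Unweighted ordinary least squares of reference CCS on drift time.
#'
#' @param series a [calibrant_series()].
#' @return object of class `calibration_model`: `slope` (angstrom^2/ms),
#'   `intercept` (angstrom^2), `r_squared`, `n_points`, plus the input
#'   `series` and per-point `residuals`.
#' @export
fit_calibration <- function(series) {
  if (!inherits(series, "calibrant_series")) {
    series <- calibrant_series(
      series$species %||% seq_len(nrow(series)),
      series$drift_time, series$reference_ccs
    )
  }
  fit <- lm(reference_ccs ~ drift_time, data = series)
  sst <- sum((series$reference_ccs - mean(series$reference_ccs))^2)
  ssr <- sum(stats::residuals(fit)^2)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = if (sst > 0) 1 - ssr / sst else 1,
      n_points = nrow(series),
      series = series,
      residuals = unname(stats::residuals(fit))
    ),
    class = "calibration_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Calibration: CCS = %.4g x t + %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Apply a calibration line to analyte drift times
#'
#' @param model a fitted `calibration_model`.
#' @param drift_times drift times in ms (non-negative).
#' @return CCS values in angstrom^2 at full precision (round only when
#'   rendering tables).
#' @export
apply_calibration <- function(model, drift_times) {
  stopifnot(inherits(model, "calibration_model"))
  drift_times <- as.numeric(drift_times)
  if (any(drift_times < 0)) stop("negative drift time")
  model$slope * drift_times + model$intercept
}

#' Calibration summary report
#'
#' @param model a `calibration_model` fitted on `series`.
#' @return list with the fitted line, `r_squared`, `n_points` and a
#'   per-calibrant table (species, drift time, reference and fitted CCS,
#'   residual); `format()`/`print()` give a human-readable rendering.
#' @export
calibration_report <- function(model) {
  stopifnot(inherits(model, "calibration_model"))
  tab <- data.frame(
    species = model$series$species,
    drift_time = model$series$drift_time,
    reference_ccs = model$series$reference_ccs,
    fitted_ccs = apply_calibration(model, model$series$drift_time),
    residual = model$residuals
  )
  structure(
    list(
      slope = model$slope, intercept = model$intercept,
      r_squared = model$r_squared, n_points = model$n_points,
      table = tab
    ),
    class = "calibration_report"
  )
}

#' @export
format.calibration_report <- function(x, ...) {
  c(
    sprintf(
      "CCS = %.1f x t + %.0f  (R^2 = %.3f, n = %d)",
      x$slope, x$intercept, x$r_squared, x$n_points
    ),
    sprintf(
      "  %-10s t=%5.2f ms  ref=%6.1f  fit=%6.1f  resid=%+5.2f",
      x$table$species, x$table$drift_time, x$table$reference_ccs,
      x$table$fitted_ccs, x$table$residual
    )
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
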