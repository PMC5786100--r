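# Experiment-vs-computation comparison statistics for per-glycan CCS
# tables: signed percentage differences, per-state Pearson correlations,
# protonation-state CCS shifts, and isomeric-pair CCS separations.

#' Signed percentage difference between calculated and experimental CCS
#'
#' `(calc - exp) / exp * 100`.  The sign is kept; render magnitudes where a
#' table prints them.
#'
#' @param calc,exp CCS values (angstrom^2); `exp` must be positive.
#' @return signed percentage difference(s).
#' @export
percent_difference <- function(calc, exp) {
  if (any(exp <= 0, na.rm = TRUE)) stop("experimental CCS must be positive")
  (calc - exp) / exp * 100
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (n >= 3) with non-zero variance.
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3")
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Per-glycan comparison records
#'
#' @param glycan glycan ids.
#' @param exp experimental CCS (angstrom^2).
#' @param p3,p6 calculated CCS per protonation state (`NA` where a state
#'   was not modeled).
#' @return data frame of class `comparison_records` with signed
#'   `pct_diff_p3` / `pct_diff_p6` columns appended.
#' @export
comparison_records <- function(glycan, exp, p3, p6) {
  out <- data.frame(
    glycan = as.character(glycan), exp = exp, p3 = p3, p6 = p6
  )
  out$pct_diff_p3 <- ifelse(is.na(out$p3), NA,
    percent_difference(out$p3, out$exp)
  )
  out$pct_diff_p6 <- ifelse(is.na(out$p6), NA,
    percent_difference(out$p6, out$exp)
  )
  class(out) <- c("comparison_records", "data.frame")
  out
}

#' Per-state comparison statistics
#'
#' For each protonation state: the Pearson correlation of calculated
#' against experimental CCS over all glycans (a glycan modeled in a single
#' state contributes its only calculated value to both regressions) and
#' the average percentage-difference magnitude over the values present in
#' that state's column.
#'
#' @param records a [comparison_records()].
#' @return list with `r_p3`, `r_p6`, `avg_pct_diff_p3`, `avg_pct_diff_p6`,
#'   and the series used.
#' @export
state_statistics <- function(records) {
  stopifnot(inherits(records, "comparison_records"))
  p3_series <- ifelse(is.na(records$p3), records$p6, records$p3)
  p6_series <- ifelse(is.na(records$p6), records$p3, records$p6)
  list(
    r_p3 = pearson_r(records$exp, p3_series),
    r_p6 = pearson_r(records$exp, p6_series),
    avg_pct_diff_p3 = mean(abs(records$pct_diff_p3), na.rm = TRUE),
    avg_pct_diff_p6 = mean(abs(records$pct_diff_p6), na.rm = TRUE),
    p3_series = p3_series,
    p6_series = p6_series
  )
}

#' CCS shift between protonation states
#'
#' Absolute CCS differences |P3 - P6| over the glycans modeled in both
#' states.
#'
#' @param records a [comparison_records()].
#' @return list: `per_glycan` (named |delta|), `mean`, `max_glycan`,
#'   `min_glycan`.
#' @export
protonation_delta <- function(records) {
  stopifnot(inherits(records, "comparison_records"))
  both <- !is.na(records$p3) & !is.na(records$p6)
  if (!any(both)) stop("no glycan modeled in both protonation states")
  d <- abs(records$p3[both] - records$p6[both])
  names(d) <- records$glycan[both]
  list(
    per_glycan = d,
    mean = mean(d),
    max_glycan = names(d)[which.max(d)],
    min_glycan = names(d)[which.min(d)]
  )
}

#' CCS separation of isomeric glycan pairs
#'
#' Globular-minus-rod CCS difference per isomer pair, for both calculated
#' (at the requested protonation state of each member) and experimental
#' values.
#'
#' @param records a [comparison_records()].
#' @param pairs data frame with columns `id`, `globular`, `globular_state`
#'   (`"p3"`/`"p6"`), `rod`, `rod_state`.
#' @return data frame: `id`, `calc_delta`, `exp_delta`.
#' @export
isomer_separation <- function(records, pairs) {
  stopifnot(inherits(records, "comparison_records"))
  need <- c("id", "globular", "globular_state", "rod", "rod_state")
  if (!all(need %in% names(pairs))) {
    stop("pairs needs columns: ", paste(need, collapse = ", "))
  }
  pick <- function(glycan, state) {
    i <- match(glycan, records$glycan)
    if (is.na(i)) stop("glycan not in records: ", glycan)
    v <- records[[state]][i]
    if (is.na(v)) stop("no ", state, " value for ", glycan)
    v
  }
  calc <- vapply(seq_len(nrow(pairs)), function(k) {
    pick(pairs$globular[k], pairs$globular_state[k]) -
      pick(pairs$rod[k], pairs$rod_state[k])
  }, 0)
  expd <- vapply(seq_len(nrow(pairs)), function(k) {
    records$exp[match(pairs$globular[k], records$glycan)] -
      records$exp[match(pairs$rod[k], records$glycan)]
  }, 0)
  data.frame(id = pairs$id, calc_delta = calc, exp_delta = expd)
}

#' Packaged isomer pairs for the reference glycan panel
#'
#' The three isomeric pairs and the protonation state of each member used
#' to reconstruct their CCS separations: the shorter-alpha1-6-arm member
#' of each pair is the compact globular form.
#'
#' @return data frame usable as `pairs` in [isomer_separation()].
#' @export
reference_isomer_pairs <- function() {
  data.frame(
    id = c("G0F-GN", "G1", "G1F"),
    globular = c("G0F-GN(3)", "G1(3)", "G1F(3)"),
    globular_state = c("p3", "p3", "p3"),
    rod = c("G0F-GN(6)", "G1(6)", "G1F(6)"),
    rod_state = c("p6", "p3", "p6")
  )
}
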