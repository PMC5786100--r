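# Accessors for the packaged reference tables: the doubly protonated
# polyalanine calibrant ladder, the glycan drift times measured in N2, and
# the published experiment-vs-computation CCS comparison for the ten
# PA-glycan panel.

#' Polyalanine calibrant ladder
#'
#' Doubly protonated polyalanine (chain lengths 11-15) drift times with
#' absolute reference CCS in N2; the five-point basis of the linear
#' drift-time calibration.
#'
#' @return a [calibrant_series()].
#' @export
polyalanine_calibrants <- function() {
  read_calibrant_table(system.file("extdata", "polyalanine_calibrants.csv",
    package = "glycoccs", mustWork = TRUE
  ))
}

#' Measured glycan drift times
#'
#' Drift times of the ten doubly protonated PA-glycans in N2, with the
#' reported calibrated CCS for reference.
#'
#' @return data frame: `species`, `mz`, `drift_ms`, `reported_ccs_A2`.
#' @export
glycan_drift_times <- function() {
  read.table(
    system.file("extdata", "glycan_drift_times.csv",
      package = "glycoccs", mustWork = TRUE
    ),
    header = TRUE, sep = ",", strip.white = TRUE
  )
}

#' Published CCS comparison for the glycan panel
#'
#' Experimental N2 CCS and ensemble-averaged calculated CCS per protonation
#' state (P3: proton on the alpha1-3-branch GlcNAc; P6: alpha1-6 branch)
#' for the ten-glycan panel, in N2.  He-gas calculated values ride along in
#' the attribute `he`.
#'
#' @return a [comparison_records()] for the N2 columns.
#' @export
glycan_ccs_comparison <- function() {
  tab <- read.table(
    system.file("extdata", "glycan_ccs_comparison.csv",
      package = "glycoccs", mustWork = TRUE
    ),
    header = TRUE, sep = ",", strip.white = TRUE, na.strings = "NA"
  )
  rec <- comparison_records(tab$glycan, tab$exp_n2, tab$calc_n2_p3,
    tab$calc_n2_p6)
  attr(rec, "he") <- tab[, c("glycan", "calc_he_p3", "calc_he_p6")]
  rec
}
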