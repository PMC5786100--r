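# Buffer-gas models and Monte Carlo controls for the CCS engines.

#' Buffer-gas model
#'
#' Loads the per-gas physics (mass, polarizability) and per-element
#' interaction parameters (Lennard-Jones well depth and distance, hard-
#' sphere collision radius) used by both CCS engines.  The packaged table
#' (`inst/extdata/gas_params.yaml`) treats N2 as a single isotropic
#' pseudo-atom; pass `params_file` to substitute a calibrated set.
#'
#' @param gas `"N2"` or `"He"`.
#' @param temperature buffer-gas temperature in kelvin (default 300).
#' @param params_file optional YAML file with the same layout as the
#'   packaged one.
#' @return object of class `gas_model`: `name`, `mass` (amu),
#'   `polarizability` (angstrom^3), `temperature` (K), `elements` (data
#'   frame: element, eps (eV), sigma (angstrom), rhs (angstrom)).
#' @export
gas_model <- function(gas = c("N2", "He"), temperature = 300,
                      params_file = NULL) {
  gas <- match.arg(gas)
  if (temperature <= 0) stop("temperature must be positive")
  if (is.null(params_file)) {
    params_file <- system.file("extdata", "gas_params.yaml",
      package = "glycoccs", mustWork = TRUE
    )
  }
  cfg <- yaml::read_yaml(params_file)
  if (is.null(cfg[[gas]])) stop("gas '", gas, "' not in parameter file")
  g <- cfg[[gas]]
  els <- g$elements
  elements <- data.frame(
    element = names(els),
    eps = vapply(els, function(e) as.numeric(e$eps), 0),
    sigma = vapply(els, function(e) as.numeric(e$sigma), 0),
    rhs = vapply(els, function(e) as.numeric(e$rhs), 0),
    row.names = NULL
  )
  if (any(!is.finite(as.matrix(elements[, -1])))) {
    stop("incomplete interaction parameters for gas ", gas)
  }
  structure(
    list(
      name = gas,
      mass = as.numeric(g$mass),
      polarizability = as.numeric(g$polarizability),
      temperature = temperature,
      elements = elements
    ),
    class = "gas_model"
  )
}

#' @export
print.gas_model <- function(x, ...) {
  cat(sprintf(
    "Gas model %s: mass %.4f amu, alpha %.4f A^3, T %.1f K, %d element(s)\n",
    x$name, x$mass, x$polarizability, x$temperature, nrow(x$elements)
  ))
  invisible(x)
}

# per-atom parameter lookup; radius_override (if any) replaces rhs
.gas_atom_params <- function(elements, gas, what, override = NULL) {
  i <- match(elements, gas$elements$element)
  if (any(is.na(i))) {
    stop(
      "gas '", gas$name, "' lacks interaction parameters for element(s): ",
      paste(unique(elements[is.na(i)]), collapse = ", ")
    )
  }
  out <- gas$elements[[what]][i]
  if (!is.null(override)) {
    out[!is.na(override)] <- override[!is.na(override)]
  }
  out
}

#' Monte Carlo and integrator controls for the trajectory method
#'
#' @param n_integration_points samples of (orientation, impact parameter,
#'   relative speed) per Monte Carlo cycle; default 25.
#' @param max_cycles cap on cycles; cycles repeat until the standard error
#'   falls below `se_target_rel` of the running mean or the cap is hit.
#' @param se_target_rel relative standard-error stopping target (default
#'   0.01).
#' @param error_tol local error tolerance of the adaptive Runge-Kutta
#'   integrator.
#' @param energy_tol relative energy-drift tolerance per trajectory; a
#'   trajectory exceeding it is re-integrated with a tighter step control.
#' @param start_pad extra start distance beyond the molecular extent plus
#'   the largest sigma (angstrom).
#' @param b_max_pad impact-parameter headroom beyond extent + sigma_max
#'   (angstrom).
#' @param max_steps step budget per trajectory; exhaustion marks the
#'   trajectory non-escaping (orbiting) and it is resampled.
#' @param seed integer seed for the Monte Carlo sampler.
#' @return list of class `trajectory_params`.
#' @export
trajectory_params <- function(n_integration_points = 25, max_cycles = 40,
                              se_target_rel = 0.01, error_tol = 1e-10,
                              energy_tol = 1e-6, start_pad = 15,
                              b_max_pad = 10, max_steps = 500000,
                              seed = 1) {
  stopifnot(
    n_integration_points >= 1, max_cycles >= 2, error_tol > 0,
    energy_tol > 0, start_pad > 0, b_max_pad > 0, max_steps > 1000
  )
  structure(
    list(
      n_integration_points = as.integer(n_integration_points),
      max_cycles = as.integer(max_cycles),
      se_target_rel = se_target_rel,
      error_tol = error_tol,
      energy_tol = energy_tol,
      start_pad = start_pad,
      b_max_pad = b_max_pad,
      max_steps = as.integer(max_steps),
      seed = as.integer(seed)
    ),
    class = "trajectory_params"
  )
}
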