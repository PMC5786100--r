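# Trajectory-method CCS: Monte Carlo momentum-transfer collision integral
# over buffer-gas scattering trajectories in the Lennard-Jones +
# ion-induced-dipole potential.

#' Probe-molecule interaction potential
#'
#' Energy and exact force on a buffer-gas pseudo-atom at `probe`:
#' pairwise 12-6 Lennard-Jones terms per atom plus the ion-induced-dipole
#' attraction \eqn{-(\alpha/2)\,|\sum_i q_i \hat r_i / r_i^2|^2} from the
#' per-atom partial charges and the gas polarizability.
#'
#' @param coords N x 3 coordinates (angstrom).
#' @param elements length-N element symbols.
#' @param probe length-3 gas position (angstrom).
#' @param gas a [gas_model()].
#' @param charges per-atom charges in e (default all zero; the induced-
#'   dipole term then vanishes).
#' @return list with `energy` (eV) and `force` (length-3, eV/angstrom).
#' @export
interaction_potential <- function(coords, elements, probe, gas,
                                  charges = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(elements), length(probe) == 3)
  if (is.null(charges)) charges <- rep(0, nrow(coords))
  eps <- .gas_atom_params(elements, gas, "eps")
  sigma <- .gas_atom_params(elements, gas, "sigma")
  cpp_interaction_potential(
    coords, eps, sigma, as.numeric(charges),
    gas$polarizability, as.numeric(probe)
  )
}

#' Propagate one buffer-gas scattering trajectory
#'
#' Integrates the classical motion of the gas pseudo-atom (reduced mass of
#' the gas-molecule pair) from an asymptotic start state through the
#' interaction potential until it re-enters the asymptotic region, with an
#' adaptive Runge-Kutta (Cash-Karp 4/5) integrator.  The scattering angle
#' chi is the angle between the incoming and outgoing velocity; total
#' energy is conserved within `params$energy_tol` (relative) or the
#' trajectory is re-integrated with tighter step control.
#'
#' @param coords N x 3 molecule coordinates (angstrom), any frame.
#' @param elements length-N element symbols.
#' @param gas a [gas_model()].
#' @param position,velocity start state (angstrom, angstrom/ps).
#' @param charges per-atom charges in e (default zero).
#' @param params a [trajectory_params()].
#' @param r_escape escape radius (angstrom); default the start radius.
#' @return list: `chi` (radians), `escaped` (FALSE marks an orbiting,
#'   step-budget-exhausted trajectory the caller should resample),
#'   `energy_drift` (relative), `n_steps`.
#' @export
propagate_trajectory <- function(coords, elements, gas, position, velocity,
                                 charges = NULL,
                                 params = trajectory_params(),
                                 r_escape = NULL) {
  coords <- as.matrix(coords)
  if (is.null(charges)) charges <- rep(0, nrow(coords))
  if (is.null(r_escape)) r_escape <- sqrt(sum(position^2)) - 1e-9
  eps <- .gas_atom_params(elements, gas, "eps")
  sigma <- .gas_atom_params(elements, gas, "sigma")
  mu <- .reduced_mass(elements, gas)
  cpp_propagate(
    coords, eps, sigma, as.numeric(charges), gas$polarizability, mu,
    as.numeric(position), as.numeric(velocity),
    params$error_tol, params$energy_tol, params$max_steps, r_escape
  )
}

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, He = 4.002602
)

.reduced_mass <- function(elements, gas) {
  m_mol <- sum(.atomic_masses[elements], na.rm = TRUE)
  if (!all(elements %in% names(.atomic_masses))) {
    m_mol <- m_mol + 12.011 * sum(!elements %in% names(.atomic_masses))
  }
  gas$mass * m_mol / (gas$mass + m_mol)
}

# draw a relative speed from the Omega^(1,1) collision-integral weight
# p(gamma) = gamma^5 exp(-gamma^2): gamma^2 ~ Gamma(3, 1)
.draw_speed <- function(mu, temperature) {
  x <- -log(runif(1)) - log(runif(1)) - log(runif(1))
  sqrt(2 * x * .kB_eV * temperature / (mu * .EV_PER_AMU_A2_PS2))
}

#' Trajectory-method collision cross section
#'
#' Monte Carlo estimate of the temperature-averaged momentum-transfer
#' collision integral
#' \eqn{\Omega = \pi b_{max}^2 \langle 1 - \cos\chi \rangle},
#' averaging over uniformly random molecular orientations, area-uniform
#' impact parameters on \eqn{[0, b_{max}]}, and relative speeds drawn from
#' the Maxwell-Boltzmann collision-integral weight at the gas temperature
#' and reduced mass.  Cycles of `n_integration_points` samples repeat until
#' the standard error over cycle means drops below `se_target_rel` of the
#' running mean or `max_cycles` is reached.  Non-escaping (orbiting)
#' trajectories are resampled and counted.
#'
#' @param coords N x 3 coordinates (angstrom).
#' @param elements length-N element symbols.
#' @param gas a [gas_model()].
#' @param charges per-atom charges in e (default zero, with a warning:
#'   the induced-dipole term vanishes).
#' @param params a [trajectory_params()]; its `seed` drives all sampling.
#' @param quiet suppress the zero-charge warning.
#' @return a `ccs_result` with `omega` (angstrom^2), `standard_error`,
#'   `n_samples` (trajectories), `n_failed` (non-escaping draws),
#'   `max_energy_drift`, `b_max`.
#' @export
ccs_trajectory <- function(coords, elements, gas, charges = NULL,
                           params = trajectory_params(), quiet = FALSE) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(elements), ncol(coords) == 3)
  if (is.null(charges)) {
    if (!quiet) {
      warning("no partial charges given; induced-dipole term is zero")
    }
    charges <- rep(0, nrow(coords))
  }
  eps <- .gas_atom_params(elements, gas, "eps")
  sigma <- .gas_atom_params(elements, gas, "sigma")
  mu <- .reduced_mass(elements, gas)
  coords <- sweep(coords, 2, colMeans(coords))
  extent <- sqrt(max(rowSums(coords^2)))
  b_max <- extent + max(sigma) + params$b_max_pad
  z0 <- extent + max(sigma) + params$start_pad
  r_start <- sqrt(b_max^2 + z0^2)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(params$seed)

  cycle_means <- numeric(0)
  n_failed <- 0L
  max_drift <- 0
  n_traj <- 0L
  for (cyc in seq_len(params$max_cycles)) {
    vals <- numeric(params$n_integration_points)
    for (i in seq_len(params$n_integration_points)) {
      repeat {
        rot <- .random_rotation()
        b <- b_max * sqrt(runif(1))
        g <- .draw_speed(mu, gas$temperature)
        res <- cpp_propagate(
          coords %*% t(rot), eps, sigma, charges, gas$polarizability, mu,
          c(b, 0, -z0), c(0, 0, g),
          params$error_tol, params$energy_tol, params$max_steps,
          r_start - 1e-9
        )
        if (res$escaped) break
        n_failed <- n_failed + 1L
      }
      n_traj <- n_traj + 1L
      max_drift <- max(max_drift, res$energy_drift)
      vals[i] <- 1 - cos(res$chi)
    }
    cycle_means <- c(cycle_means, pi * b_max^2 * mean(vals))
    if (cyc >= 3) {
      omega <- mean(cycle_means)
      se <- sd(cycle_means) / sqrt(cyc)
      if (omega > 0 && se < params$se_target_rel * omega) break
    }
  }
  omega <- mean(cycle_means)
  se <- sd(cycle_means) / sqrt(length(cycle_means))
  warn <- NULL
  if (n_failed > 0.01 * n_traj) {
    warn <- sprintf(
      "%d of %d trajectories were non-escaping (orbiting)",
      n_failed, n_traj + n_failed
    )
    warning(warn)
  }
  structure(
    list(
      method = "trajectory",
      gas = gas$name,
      omega = omega,
      standard_error = se,
      n_samples = n_traj,
      n_failed = n_failed,
      max_energy_drift = max_drift,
      b_max = b_max,
      warning = warn
    ),
    class = "ccs_result"
  )
}

#' CCS for selected conformers of an ensemble
#'
#' Runs one CCS engine per requested conformer with a per-conformer seed
#' derived from the base seed and the conformer index, so results are
#' reproducible and independent of the request order.
#'
#' @param ensemble a [conformer_ensemble()]; `atoms$charge` supplies the
#'   partial charges for the trajectory method.
#' @param indices 0-based conformer indices (duplicates allowed).
#' @param method `"projection"` or `"trajectory"`.
#' @param gas a [gas_model()].
#' @param params a [trajectory_params()] (its seed is the base seed; also
#'   used, with `n_integration_points`-scaled defaults, for projection).
#' @param ... passed to the engine ([ccs_projection()] arguments for the
#'   projection method).
#' @return list of `ccs_result`, one per requested index.
#' @export
ccs_for_conformers <- function(ensemble, indices,
                               method = c("projection", "trajectory"),
                               gas, params = trajectory_params(), ...) {
  method <- match.arg(method)
  m <- n_conformers(ensemble)
  if (any(indices < 0 | indices >= m)) stop("conformer index out of range")
  elements <- ensemble$atoms$element
  charges <- ensemble$atoms$charge
  lapply(indices, function(i) {
    seed_i <- (params$seed + 1000003L * (i + 1L)) %% 2147483647L
    x <- ensemble$coords[[i + 1L]]
    if (method == "projection") {
      ccs_projection(x, elements, gas,
        seed = seed_i,
        radius_override = ensemble$atoms$radius_override, ...
      )
    } else {
      p <- params
      p$seed <- seed_i
      ccs_trajectory(x, elements, gas,
        charges = charges, params = p,
        quiet = TRUE
      )
    }
  })
}
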