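# Synthetic fixtures with full ground truth: calibrant series on a known
# line, mixture ensembles of rigid states, branched bead-chain glycan
# mimics, and planted hydrogen-bond geometries.
#
# Bead "residues" are 3-atom rigid groups (C, O, H) rather than real sugar
# geometry; the pipeline only ever inspects elements, charges, coordinates
# and unit labels.  Every generator consumes its random stream in a
# documented order (state labels first, then coordinate noise) so ground
# truth is reproducible from the seed alone.

#' Synthetic calibrant series on a known line
#'
#' Drift times evenly spaced over `drift_range`; reference CCS follows
#' `slope * t + intercept` plus Gaussian noise.
#'
#' @param slope true slope (angstrom^2/ms).
#' @param intercept true intercept (angstrom^2).
#' @param n number of calibrants (>= 2).
#' @param drift_range drift-time range in ms, length 2.
#' @param noise_sd Gaussian CCS noise (angstrom^2, >= 0).
#' @param seed integer seed.
#' @return list with `series` (a [calibrant_series()]) and `ground_truth`
#'   (`slope`, `intercept`, `noise_sd`).
#' @export
make_calibrants <- function(slope, intercept, n = 10,
                            drift_range = c(3, 6), noise_sd = 0, seed = 1) {
  if (n < 2) stop("need at least two calibrants")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(drift_range) != 2 || drift_range[1] <= 0 ||
    drift_range[2] <= drift_range[1]) {
    stop("invalid drift range")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  t <- seq(drift_range[1], drift_range[2], length.out = n)
  ccs <- slope * t + intercept + rnorm(n, 0, noise_sd)
  list(
    series = calibrant_series(sprintf("cal%02d", seq_len(n)), t, ccs),
    ground_truth = list(slope = slope, intercept = intercept,
      noise_sd = noise_sd)
  )
}

# reference bead-chain conformation: a gentle helix (never collinear)
.bead_chain <- function(n_atoms, spacing = 3.8) {
  i <- seq_len(n_atoms) - 1
  cbind(2.2 * cos(i * 0.7), 2.2 * sin(i * 0.7), i * spacing)
}

# hinge the second half of a chain about the y-axis at the midpoint
.hinged_chain <- function(base, phi) {
  n <- nrow(base)
  half <- floor(n / 2)
  out <- base
  pivot <- base[half, ]
  rot <- matrix(c(
    cos(phi), 0, sin(phi),
    0, 1, 0,
    -sin(phi), 0, cos(phi)
  ), 3, 3, byrow = TRUE)
  rest <- (half + 1):n
  out[rest, ] <- sweep(sweep(base[rest, , drop = FALSE], 2, pivot) %*% t(rot),
    2, pivot, `+`
  )
  out
}

#' Two-state mixture ensemble with known populations
#'
#' Builds two rigid reference conformations of a bead chain whose pairwise
#' best-fit RMSD equals `rmsd_separation` (within 5 percent; a hinge angle
#' is solved for by bisection), then draws conformers from the mixture with
#' per-atom Gaussian noise.  The random stream is consumed labels-first,
#' then noise.
#'
#' @param n_frames conformers to draw.
#' @param weight_a mixture weight of state A in `[0, 1]`.
#' @param rmsd_separation target inter-state RMSD (angstrom).
#' @param noise_sd per-coordinate Gaussian noise (angstrom).
#' @param n_atoms beads in the chain (default 20).
#' @param seed integer seed.
#' @return list with `ensemble` (a [conformer_ensemble()], labels "A"/"B")
#'   and `ground_truth` (`state_labels`, `weight_a`, `counts`,
#'   `reference_coords`, `realized_separation`).
#' @export
make_two_state_ensemble <- function(n_frames, weight_a = 0.6,
                                    rmsd_separation = 10, noise_sd = 0.1,
                                    n_atoms = 20, seed = 1) {
  stopifnot(n_frames >= 1, weight_a >= 0, weight_a <= 1, noise_sd >= 0)
  if (rmsd_separation <= 0) stop("separation must be positive")
  a <- .bead_chain(n_atoms)
  sep_of <- function(phi) rmsd(a, .hinged_chain(a, phi), fit = TRUE)
  max_sep <- max(vapply(seq(0.1, pi, length.out = 40), sep_of, 0))
  if (rmsd_separation > max_sep) {
    stop(sprintf(
      "separation %.1f A unattainable for a %d-bead chain (max %.1f A)",
      rmsd_separation, n_atoms, max_sep
    ))
  }
  lo <- 0
  hi <- pi
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (sep_of(mid) < rmsd_separation) lo <- mid else hi <- mid
  }
  b <- .hinged_chain(a, (lo + hi) / 2)
  realized <- rmsd(a, b, fit = TRUE)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  states <- sample(c("A", "B"), n_frames,
    replace = TRUE,
    prob = c(weight_a, 1 - weight_a)
  )
  coords <- lapply(states, function(s) {
    ref <- if (s == "A") a else b
    ref + matrix(rnorm(3 * n_atoms, 0, noise_sd), ncol = 3)
  })
  atoms <- data.frame(
    element = rep("C", n_atoms),
    atom_name = sprintf("C%d", seq_len(n_atoms)),
    residue_index = seq_len(n_atoms),
    residue_name = "BEA",
    charge = 0,
    radius_override = NA_real_
  )
  list(
    ensemble = conformer_ensemble(atoms, coords, labels = states),
    ground_truth = list(
      state_labels = states,
      weight_a = weight_a,
      counts = c(A = sum(states == "A"), B = sum(states == "B")),
      reference_coords = list(A = a, B = b),
      realized_separation = realized
    )
  )
}

# one bead residue: C at p, O bonded to C, H on O
.bead_residue <- function(p, u) {
  # u: unit direction used to orient the O-H group
  v <- c(-u[2], u[1], 0)
  if (sqrt(sum(v^2)) < 1e-8) v <- c(1, 0, 0)
  v <- v / sqrt(sum(v^2))
  o <- p + 1.43 * v
  h <- o + 0.96 * (0.6 * v + 0.8 * u) / sqrt(sum((0.6 * v + 0.8 * u)^2))
  rbind(p, o, h)
}

#' Branched glycan-mimic ensemble with unit annotation
#'
#' Builds a branched bead-residue chain emulating an N-glycan topology: a
#' PA-tag bead at the reducing end, a linear chitobiose-like core, two arms
#' branching from the core terminus, and an optional fucose bead on the
#' first core residue.  Each residue is a rigid C/O/H group, so the mimic
#' carries hydrogen-bond donors and acceptors.  Geometry is self-avoiding
#' (no two atoms of different residues closer than 1.5 angstrom); arm
#' directions are jittered and retried (seeded) if a clash occurs.
#'
#' @param core_length core residues (>= 1).
#' @param arm13_length,arm16_length arm lengths in residues (>= 1).
#' @param fucose attach a fucose bead?
#' @param n_conformers conformers to emit (noise-jittered copies).
#' @param noise_sd per-coordinate Gaussian noise for conformers 2..M.
#' @param seed integer seed.
#' @return list with `ensemble` and `annotation` (a `residue_annotation`).
#' @export
make_glycan_mimic <- function(core_length = 2, arm13_length = 3,
                              arm16_length = 2, fucose = TRUE,
                              n_conformers = 1, noise_sd = 0, seed = 1) {
  stopifnot(core_length >= 1, arm13_length >= 1, arm16_length >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  spacing <- 4.2
  for (attempt in 1:20) {
    jit <- if (attempt == 1) c(0, 0) else runif(2, -0.3, 0.3)
    centers <- list()
    units <- character(0)
    dirs <- list()
    # PA tag below the core
    centers[[1]] <- c(0, 0, -spacing)
    dirs[[1]] <- c(0, 0, -1)
    units[1] <- "PA-tag"
    for (i in seq_len(core_length)) {
      centers[[length(centers) + 1]] <- c(0, 0, (i - 1) * spacing)
      dirs[[length(dirs) + 1]] <- c(0, 0, 1)
      units <- c(units, "core-chitobiose")
    }
    branch <- c(0, 0, (core_length - 1) * spacing)
    d13 <- c(sin(pi / 3 + jit[1]), 0, cos(pi / 3 + jit[1]))
    d16 <- c(-sin(pi / 3 + jit[2]), 0, cos(pi / 3 + jit[2]))
    for (i in seq_len(arm13_length)) {
      centers[[length(centers) + 1]] <- branch + i * spacing * d13
      dirs[[length(dirs) + 1]] <- d13
      units <- c(units, "alpha1-3-arm")
    }
    for (i in seq_len(arm16_length)) {
      centers[[length(centers) + 1]] <- branch + i * spacing * d16
      dirs[[length(dirs) + 1]] <- d16
      units <- c(units, "alpha1-6-arm")
    }
    if (fucose) {
      centers[[length(centers) + 1]] <- c(0, spacing, 0)
      dirs[[length(dirs) + 1]] <- c(0, 1, 0)
      units <- c(units, "fucose")
    }
    n_res <- length(centers)
    coords <- do.call(rbind, lapply(seq_len(n_res), function(i) {
      .bead_residue(centers[[i]], dirs[[i]])
    }))
    resno <- rep(seq_len(n_res), each = 3)
    d <- as.matrix(stats::dist(coords))
    inter <- outer(resno, resno, `!=`)
    if (min(d[inter]) >= 1.5) break
    if (attempt == 20) stop("self-avoidance retries exhausted")
  }
  atoms <- data.frame(
    element = rep(c("C", "O", "H"), n_res),
    atom_name = rep(c("C1", "O1", "HO1"), n_res),
    residue_index = resno,
    residue_name = rep(
      c("PAT", "COR", "A13", "A16", "FUC")[match(
        units,
        c("PA-tag", "core-chitobiose", "alpha1-3-arm", "alpha1-6-arm", "fucose")
      )],
      each = 3
    ),
    charge = 0,
    radius_override = NA_real_
  )
  conf <- vector("list", n_conformers)
  conf[[1]] <- coords
  if (n_conformers > 1) {
    # residues are rigid groups: noise displaces whole residues, never
    # distorts covalent O-H geometry
    for (mi in 2:n_conformers) {
      shift <- matrix(rnorm(3 * n_res, 0, noise_sd), ncol = 3)
      conf[[mi]] <- coords + shift[resno, ]
    }
  }
  list(
    ensemble = conformer_ensemble(atoms, conf),
    annotation = residue_annotation(seq_len(n_res), units)
  )
}

#' Plant a hydrogen bond at an exact geometry
#'
#' Adds an O-H donor group (assigned to `donor_residue`) and an acceptor O
#' (assigned to `acceptor_residue`) outside the molecule so the realized
#' heavy-atom distance R and donor-centered angle theta equal the request
#' to machine precision.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param conformer 0-based conformer to modify (the same atoms are added
#'   to every conformer; other conformers park the group at the same site).
#' @param donor_residue,acceptor_residue existing residue indices
#'   (distinct).
#' @param r heavy-atom distance R_XY (angstrom).
#' @param theta donor-centered angle theta_HXY (degrees).
#' @return the modified ensemble, with attribute `planted` recording the
#'   0-based indices of the new donor, hydrogen and acceptor atoms.
#' @export
plant_hbond <- function(ensemble, conformer = 0, donor_residue,
                        acceptor_residue, r, theta) {
  stopifnot(r > 1.5, r < 10, theta >= 0, theta < 90)
  if (donor_residue == acceptor_residue) {
    stop("donor and acceptor residues must differ")
  }
  res <- ensemble$atoms$residue_index
  if (!donor_residue %in% res || !acceptor_residue %in% res) {
    stop("residue not present in ensemble")
  }
  x <- ensemble$coords[[conformer + 1L]]
  cm <- colMeans(x)
  cd <- colMeans(x[res == donor_residue, , drop = FALSE])
  u <- cd - cm
  nu <- sqrt(sum(u^2))
  u <- if (nu < 1e-8) c(0, 0, 1) else u / nu
  extent <- sqrt(max(rowSums(sweep(x, 2, cm)^2)))
  # place the group clear of the molecule along the donor-residue
  # direction; rotate deterministically about z until collision-free
  if (abs(u[1]) + abs(u[2]) < 1e-6) {
    u <- u + c(0.3, 0, 0) # tilt off the rotation axis
    u <- u / sqrt(sum(u^2))
  }
  axis_rot <- function(v, phi) {
    c(
      cos(phi) * v[1] - sin(phi) * v[2],
      sin(phi) * v[1] + cos(phi) * v[2],
      v[3]
    )
  }
  newxyz <- NULL
  for (k in 0:35) {
    uk <- axis_rot(u, k * pi / 18)
    xd <- cm + (extent + 5) * uk # donor heavy atom
    e1 <- uk
    e2 <- c(-uk[2], uk[1], 0)
    if (sqrt(sum(e2^2)) < 1e-8) e2 <- c(1, 0, 0)
    e2 <- e2 / sqrt(sum(e2^2))
    ya <- xd + r * e1
    th <- theta * pi / 180
    h <- xd + 0.96 * (cos(th) * e1 + sin(th) * e2)
    cand <- rbind(xd, h, ya)
    dmin <- min(vapply(
      seq_len(nrow(x)),
      function(i) min(sqrt(rowSums(sweep(cand, 2, x[i, ])^2))), 0
    ))
    if (dmin >= 1.5) {
      newxyz <- cand
      break
    }
  }
  if (is.null(newxyz)) stop("planted group collides with existing atoms")
  n0 <- nrow(ensemble$atoms)
  add <- data.frame(
    element = c("O", "H", "O"),
    atom_name = c("OD", "HD", "OA"),
    residue_index = c(donor_residue, donor_residue, acceptor_residue),
    residue_name = c("PLD", "PLD", "PLA"),
    charge = 0,
    radius_override = NA_real_
  )
  atoms <- rbind(ensemble$atoms, add)
  coords <- lapply(ensemble$coords, function(cc) rbind(cc, newxyz))
  out <- conformer_ensemble(atoms, coords, labels = ensemble$labels)
  attr(out, "planted") <- list(
    donor = n0, hydrogen = n0 + 1L, acceptor = n0 + 2L,
    r = r, theta = theta
  )
  out
}
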