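# Projection and trajectory-method CCS engines.

he <- gas_model("He")
n2 <- gas_model("N2")

test_that("projection CCS reduces to a disk for single and coincident atoms", {
  one <- ccs_projection(matrix(0, 1, 3), "C", he,
    n_orientations = 80, n_darts = 2000, seed = 2, radius_override = 2
  )
  expect_lt(abs(one$omega - 4 * pi), 3 * one$standard_error)
  # two atoms at zero separation: same disk
  two <- ccs_projection(matrix(0, 2, 3), c("C", "C"), he,
    n_orientations = 80, n_darts = 2000, seed = 2,
    radius_override = c(2, 2)
  )
  expect_lt(abs(two$omega - 4 * pi), 3 * two$standard_error)
  expect_error(
    ccs_projection(matrix(0, 1, 3), "Fe", he),
    "lacks interaction parameters"
  )
})

test_that("projected area per orientation matches a dense-grid rasterization", {
  chain <- cbind(seq(0, 6, length.out = 5), 0, 0)
  radii <- rep(2.7, 5)
  oracle <- oracle_projected_area(chain[, 1:2], radii, pitch = 0.01)
  # dart estimate of the same fixed orientation
  set.seed(5)
  darts <- replicate(40, glycoccs:::.projected_area_darts(
    chain[, 1:2], radii, 4000
  ))
  expect_lt(abs(mean(darts) - oracle) / oracle, 0.01)
})

test_that("projection CCS never decreases when an atom is added", {
  base <- cbind(seq(0, 4.5, length.out = 4), 0, 0)
  grown <- rbind(base, c(2, 5, 0))
  a <- ccs_projection(base, rep("C", 4), he,
    n_orientations = 120, n_darts = 3000, seed = 3
  )
  b <- ccs_projection(grown, rep("C", 5), he,
    n_orientations = 120, n_darts = 3000, seed = 3
  )
  expect_gt(b$omega, a$omega)
})

test_that("interaction potential has the LJ zero crossing, decay and exact gradient", {
  coords <- matrix(0, 1, 3)
  sig <- n2$elements$sigma[n2$elements$element == "C"]
  at_sigma <- interaction_potential(coords, "C", c(sig, 0, 0), n2)
  expect_equal(at_sigma$energy, 0, tolerance = 1e-14)
  far <- interaction_potential(coords, "C", c(1e4, 0, 0), n2)
  eps <- n2$elements$eps[n2$elements$element == "C"]
  expect_lt(abs(far$energy), 1e-12 * eps)
  # central-difference gradient check with charges on
  coords2 <- rbind(c(0, 0, 0), c(2, 1, -1))
  q <- c(0.7, -0.2)
  probe <- c(3.1, 2.0, 1.4)
  p0 <- interaction_potential(coords2, c("C", "O"), probe, n2, q)
  h <- 1e-5
  num <- vapply(1:3, function(k) {
    dp <- h * (1:3 == k)
    e1 <- interaction_potential(coords2, c("C", "O"), probe + dp, n2, q)$energy
    e2 <- interaction_potential(coords2, c("C", "O"), probe - dp, n2, q)$energy
    -(e1 - e2) / (2 * h)
  }, 0)
  expect_equal(p0$force, num, tolerance = 1e-6)
  expect_error(
    interaction_potential(coords, "C", c(0.05, 0, 0), n2),
    "hard core"
  )
})

test_that("scattering trajectories give chi = 0 free flight and chi = pi head-on", {
  # free flight: neutral gas with zero well depth
  zero_gas <- he
  zero_gas$elements$eps[] <- 0
  zero_gas$polarizability <- 0
  free <- propagate_trajectory(
    matrix(0, 1, 3), "C", zero_gas,
    position = c(3, 0, -20), velocity = c(0, 0, 15)
  )
  expect_true(free$escaped)
  expect_lt(free$chi, 1e-8)
  # head-on approach: purely repulsive potential (r^-12 only) realized by
  # a deep-cored LJ at energies far above the well
  head_on <- propagate_trajectory(
    matrix(0, 1, 3), "C", he,
    position = c(0, 0, -25), velocity = c(0, 0, 40)
  )
  expect_true(head_on$escaped)
  expect_equal(head_on$chi, pi, tolerance = 1e-3)
  expect_lt(head_on$energy_drift, 1e-6)
})

test_that("chi matches the classical deflection-angle quadrature", {
  eps <- he$elements$eps[he$elements$element == "C"]
  sig <- he$elements$sigma[he$elements$element == "C"]
  mu <- glycoccs:::.reduced_mass("C", he)
  for (bg in list(c(2.0, 12), c(3.5, 8), c(5.0, 15))) {
    b <- bg[1]
    g <- bg[2]
    got <- propagate_trajectory(
      matrix(0, 1, 3), "C", he,
      position = c(b, 0, -25), velocity = c(0, 0, g)
    )
    expect_true(got$escaped)
    expect_equal(got$chi, abs(oracle_chi(b, g, eps, sig, mu)),
      tolerance = 2e-3
    )
    expect_lt(got$energy_drift, 1e-6)
  }
})

test_that("trajectory CCS vanishes for a null potential and is seed-deterministic", {
  zero_gas <- he
  zero_gas$elements$eps[] <- 0
  zero_gas$polarizability <- 0
  p <- trajectory_params(n_integration_points = 10, max_cycles = 4, seed = 3)
  null <- ccs_trajectory(matrix(0, 1, 3), "C", zero_gas,
    charges = 0, params = p
  )
  expect_lt(abs(null$omega), 1e-10)
  # translation of the molecule with the same seed: identical omega
  a <- ccs_trajectory(matrix(0, 1, 3), "C", he, charges = 0, params = p)
  b <- ccs_trajectory(matrix(c(10, -5, 3), 1, 3), "C", he,
    charges = 0, params = p
  )
  expect_identical(a$omega, b$omega)
  # rerun: bitwise identical
  a2 <- ccs_trajectory(matrix(0, 1, 3), "C", he, charges = 0, params = p)
  expect_identical(a$omega, a2$omega)
  # missing charges warn once
  expect_warning(
    ccs_trajectory(matrix(0, 1, 3), "C", he, params = p),
    "induced-dipole"
  )
})

test_that("per-conformer CCS is deterministic and index-keyed", {
  sim <- make_two_state_ensemble(3, 0.5, 6, 0.05, n_atoms = 8, seed = 9)
  res <- ccs_for_conformers(sim$ensemble, c(0, 1, 2, 1),
    method = "projection",
    gas = he, params = trajectory_params(seed = 5),
    n_orientations = 40, n_darts = 800
  )
  expect_length(res, 4)
  expect_identical(res[[2]]$omega, res[[4]]$omega) # duplicate index
  res2 <- ccs_for_conformers(sim$ensemble, c(0, 1, 2, 1),
    method = "projection",
    gas = he, params = trajectory_params(seed = 5),
    n_orientations = 40, n_darts = 800
  )
  expect_identical(
    vapply(res, `[[`, 0, "omega"),
    vapply(res2, `[[`, 0, "omega")
  )
  expect_error(
    ccs_for_conformers(sim$ensemble, 5, gas = he),
    "out of range"
  )
})
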