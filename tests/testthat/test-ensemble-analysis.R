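# Superposition, RMSD/RMSF, clustering, shape descriptors.

test_that("Kabsch superposition undoes rigid transforms and matches a rotation-search oracle", {
  set.seed(21)
  ref <- matrix(rnorm(30), ncol = 3)
  # identity case
  s0 <- superpose(ref, ref)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s0$translation, rep(0, 3), tolerance = 1e-10)
  # rotated + translated copy
  th <- 0.9
  rot <- matrix(c(
    cos(th), -sin(th), 0,
    sin(th), cos(th), 0,
    0, 0, 1
  ), 3, 3, byrow = TRUE)
  mob <- sweep(ref %*% t(rot), 2, c(3, -2, 5), `+`)
  expect_lt(rmsd(ref, mob, fit = TRUE), 1e-10)
  expect_equal(det(superpose(ref, mob)$rotation), 1, tolerance = 1e-12)
  # random pair: fitted RMSD equals brute-force rotation minimization
  a <- matrix(rnorm(30), ncol = 3)
  b <- matrix(rnorm(30), ncol = 3)
  expect_equal(rmsd(a, b, fit = TRUE), oracle_min_rmsd(a, b),
    tolerance = 1e-3
  )
  # degenerate geometry
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 0.1), "collinear")
})

test_that("rmsd matches closed forms and fitting never hurts", {
  a <- matrix(rnorm(12, sd = 2), ncol = 3)
  expect_equal(rmsd(a, a), 0)
  b <- a
  b[2, 1] <- b[2, 1] + 3 # one atom displaced by 3 A among N = 4
  expect_equal(rmsd(a, b), sqrt(9 / 4))
  set.seed(8)
  for (i in 1:100) {
    x <- matrix(rnorm(15), ncol = 3)
    y <- matrix(rnorm(15), ncol = 3)
    expect_lte(rmsd(x, y, fit = TRUE), rmsd(x, y) + 1e-12)
  }
})

test_that("clustering recovers planted mixtures and exhaustive medoids", {
  # identical frames: one cluster with weight 1
  sim0 <- make_two_state_ensemble(6, 1, 8, 0, n_atoms = 10, seed = 2)
  cs0 <- cluster_ensemble(sim0$ensemble, 2.5)
  expect_length(cs0$clusters, 1)
  expect_equal(cluster_weights(cs0), 1)
  # two-state mixture: exact recovery of labels
  sim <- make_two_state_ensemble(100, 0.6, 10, 0.1, seed = 31)
  cs <- cluster_ensemble(sim$ensemble, 2.5)
  expect_length(cs$clusters, 2)
  expect_equal(
    sort(cluster_weights(cs)),
    sort(unname(sim$ground_truth$counts) / 100)
  )
  # cluster assignment refines the true state labels exactly
  expect_equal(
    max(table(cs$assignment, sim$ground_truth$state_labels) > 0),
    1
  )
  # medoids equal the exhaustive within-cluster medoid
  sim8 <- make_two_state_ensemble(8, 0.5, 9, 0.4, n_atoms = 12, seed = 5)
  cs8 <- cluster_ensemble(sim8$ensemble, 2.5)
  ref <- sim8$ensemble$coords[[1]]
  aligned <- lapply(sim8$ensemble$coords, function(x) {
    superpose(ref, x)$aligned
  })
  for (cl in cs8$clusters) {
    rows <- cl$members + 1
    if (length(rows) == 1) {
      expect_equal(cl$medoid, cl$members)
      next
    }
    dmat <- sapply(rows, function(i) {
      sapply(rows, function(j) rmsd(aligned[[i]], aligned[[j]]))
    })
    expect_equal(cl$medoid, rows[which.min(rowMeans(dmat))] - 1L)
  }
})

test_that("finer thresholds never coarsen the partition and weights always sum to 1", {
  sim <- make_two_state_ensemble(40, 0.5, 10, 0.6, seed = 13)
  coarse <- cluster_ensemble(sim$ensemble, 2.5)
  fine <- cluster_ensemble(sim$ensemble, 0.5)
  expect_gte(length(fine$clusters), length(coarse$clusters))
  for (cs in list(coarse, fine)) {
    expect_equal(sum(cluster_weights(cs)), 1, tolerance = 1e-12)
    members <- sort(unlist(lapply(cs$clusters, `[[`, "members")))
    expect_identical(members, 0:(cs$n - 1)) # partition
    # radius criterion against medoid via triangle inequality bound
    ref <- sim$ensemble$coords[[1]]
    aligned <- lapply(sim$ensemble$coords, function(x) {
      superpose(ref, x)$aligned
    })
    for (cl in cs$clusters) {
      med <- aligned[[cl$medoid + 1]]
      for (i in cl$members + 1) {
        expect_lte(rmsd(med, aligned[[i]]), 2 * cs$threshold + 1e-9)
      }
    }
  }
})

test_that("rmsf matches closed forms and the direct definition", {
  sim <- make_two_state_ensemble(5, 1, 8, 0, n_atoms = 10, seed = 3)
  expect_equal(max(rmsf(sim$ensemble)), 0, tolerance = 1e-12)
  expect_error(
    rmsf(conformer_ensemble(sim$ensemble$atoms, sim$ensemble$coords[1])),
    "at least two"
  )
  # two frames, one atom displaced by d: RMSF = d/2 for that atom...
  base <- glycoccs:::.bead_chain(12)
  moved <- base
  moved[7, ] <- moved[7, ] + c(0, 0, 1.0)
  atoms <- data.frame(
    element = rep("C", 12), atom_name = "C", residue_index = 1:12,
    residue_name = "BEA"
  )
  # ...when no refit happens; mask out the moved atom from the fit by
  # checking the direct, pre-aligned definition instead
  ens <- conformer_ensemble(atoms, list(base, moved))
  direct_mean <- (base + moved) / 2
  direct <- sqrt(rowMeans(cbind(
    rowSums((base - direct_mean)^2),
    rowSums((moved - direct_mean)^2)
  )))
  expect_equal(direct[7], 0.5)
  # package rmsf (with its superposition) agrees with the direct
  # definition for pre-aligned frames; many atoms keep the rigid-body
  # absorption of noise (6 of 3N degrees of freedom) negligible
  set.seed(17)
  big <- glycoccs:::.bead_chain(60)
  atoms60 <- data.frame(
    element = rep("C", 60), atom_name = "C", residue_index = 1:60,
    residue_name = "BEA"
  )
  frames <- lapply(1:8, function(i) big + matrix(rnorm(180, 0, 0.05), ncol = 3))
  ens2 <- conformer_ensemble(atoms60, frames)
  meanx <- Reduce(`+`, frames) / 8
  direct2 <- sqrt(Reduce(`+`, lapply(frames, function(x) {
    rowSums((x - meanx)^2)
  })) / 8)
  expect_equal(unname(rmsf(ens2)), direct2, tolerance = 0.05)
})

test_that("rmsf and shape descriptors are rigid-body invariant", {
  sim <- make_two_state_ensemble(8, 0.5, 8, 0.3, n_atoms = 10, seed = 11)
  th <- 1.1
  rot <- matrix(c(
    1, 0, 0,
    0, cos(th), -sin(th),
    0, sin(th), cos(th)
  ), 3, 3, byrow = TRUE)
  moved <- sim$ensemble
  moved$coords <- lapply(moved$coords, function(x) {
    sweep(x %*% t(rot), 2, c(5, 5, -2), `+`)
  })
  expect_equal(rmsf(sim$ensemble), rmsf(moved), tolerance = 1e-8)
  s1 <- shape_descriptor(sim$ensemble$coords[[1]])
  s2 <- shape_descriptor(moved$coords[[1]])
  expect_equal(s1$eigenvalues, s2$eigenvalues, tolerance = 1e-10)
  expect_equal(s1$kappa2, s2$kappa2, tolerance = 1e-10)
})

test_that("shape descriptor hits the rod and globular limits and the eigen oracle", {
  rod <- shape_descriptor(cbind(seq(0, 9, by = 1.5), 0, 0))
  expect_equal(rod$kappa2, 1)
  expect_equal(rod$class, "rod-like")
  tet <- shape_descriptor(rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
  ))
  expect_equal(tet$kappa2, 0, tolerance = 1e-14)
  expect_equal(tet$class, "globular")
  set.seed(19)
  cloud <- matrix(rnorm(60), ncol = 3)
  sd <- shape_descriptor(cloud)
  x0 <- sweep(cloud, 2, colMeans(cloud))
  ev <- sort(eigen(t(x0) %*% x0 / nrow(x0))$values, decreasing = TRUE)
  expect_equal(sd$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(sd$rg, sqrt(sum(ev)), tolerance = 1e-12)
  expect_error(shape_descriptor(matrix(0, 1, 3)), "two atoms")
})

test_that("weighted CCS distributions combine cluster populations correctly", {
  sim <- make_two_state_ensemble(100, 0.6, 10, 0.1, seed = 31)
  cs <- cluster_ensemble(sim$ensemble, 2.5)
  w <- cluster_weights(cs)
  d <- weighted_ccs_distribution(cs, c(400, 450))
  expect_equal(d$mean, sum(w * c(400, 450)))
  expect_equal(sum(d$masses), 1, tolerance = 1e-12)
  # single cluster: point mass
  one <- cluster_ensemble(
    make_two_state_ensemble(5, 1, 8, 0, seed = 1)$ensemble, 2.5
  )
  d1 <- weighted_ccs_distribution(one, 425)
  expect_equal(d1$mean, 425)
  expect_equal(d1$support$weight, 1)
  # relabeling invariance: mean only depends on (weight, omega) pairs
  expect_equal(
    weighted_ccs_distribution(cs, c(450, 400))$mean,
    sum(w * c(450, 400))
  )
  # fine threshold on the two-state ensemble: mass splits by state
  fine <- cluster_ensemble(sim$ensemble, 0.5)
  state_of <- sim$ground_truth$state_labels
  omega_fine <- vapply(fine$clusters, function(cl) {
    if (state_of[cl$medoid + 1] == "A") 380 else 430
  }, 0)
  df <- weighted_ccs_distribution(fine, omega_fine)
  mass_a <- sum(df$support$weight[omega_fine == 380])
  expect_lt(abs(mass_a - mean(state_of == "A")), 0.05)
})

test_that("major conformers filter and sort by population", {
  sim <- make_two_state_ensemble(100, 0.6, 10, 0.1, seed = 31)
  cs <- cluster_ensemble(sim$ensemble, 2.5)
  mc <- major_conformers(cs)
  expect_equal(nrow(mc), 2)
  expect_true(all(diff(mc$weight) <= 0))
  expect_equal(nrow(major_conformers(cs, min_fraction = 0.99)), 0)
  one <- cluster_ensemble(
    make_two_state_ensemble(4, 1, 8, 0, seed = 2)$ensemble, 2.5
  )
  expect_equal(major_conformers(one)$weight, 1)
})
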