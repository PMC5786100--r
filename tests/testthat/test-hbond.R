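# Geometric hydrogen-bond detection, occupancy maps, categories.

test_that("hydrogens attach to their nearest donor heavy atom within 1.2 A", {
  atoms <- data.frame(
    element = c("O", "H", "N", "C"),
    atom_name = c("O1", "H1", "N1", "C1"),
    residue_index = c(1, 1, 2, 2),
    residue_name = "X"
  )
  # O-H at 0.97, N at 1.05 from the same H: O wins
  x <- rbind(c(0, 0, 0), c(0.97, 0, 0), c(0.97, 1.05, 0), c(5, 5, 5))
  ens <- conformer_ensemble(atoms, list(x))
  dh <- assign_donors_hydrogens(ens)
  expect_equal(nrow(dh), 1)
  expect_equal(dh$donor, 0)
  expect_equal(dh$distance, 0.97)
  # no hydrogens
  noH <- conformer_ensemble(atoms[-2, ], list(x[-2, ]))
  expect_error(assign_donors_hydrogens(noH), "no hydrogens")
  # orphan hydrogen
  x2 <- x
  x2[2, ] <- c(3, 3, 3)
  orphan <- conformer_ensemble(atoms, list(x2))
  expect_error(assign_donors_hydrogens(orphan), "1.2 A")
})

test_that("planted geometries respect the distance and angle cutoffs", {
  mm <- make_glycan_mimic(2, 3, 2, TRUE, seed = 3)
  planted_pair <- function(ens) {
    hb <- detect_hbonds(ens, 0)
    p <- attr(ens, "planted")
    any(hb$donor == p$donor & hb$acceptor == p$acceptor)
  }
  expect_true(planted_pair(plant_hbond(mm$ensemble, 0, 2, 6, 3.4, 20)))
  expect_true(planted_pair(plant_hbond(mm$ensemble, 0, 2, 6, 3.0, 10)))
  expect_false(planted_pair(plant_hbond(mm$ensemble, 0, 2, 6, 3.6, 10)))
  expect_false(planted_pair(plant_hbond(mm$ensemble, 0, 2, 6, 3.4, 35)))
})

test_that("detection equals the exhaustive triple-scan oracle", {
  for (seed in c(3, 8, 15)) {
    mm <- make_glycan_mimic(2, 4, 3, TRUE,
      n_conformers = 3,
      noise_sd = 0.25, seed = seed
    )
    ens <- plant_hbond(mm$ensemble, 0, 2, 7, 3.2, 15)
    expect_lte(nrow(ens$atoms), 200)
    for (f in 0:2) {
      got <- detect_hbonds(ens, f)
      want <- oracle_hbond_scan(ens, f)
      expect_equal(nrow(got), nrow(want))
      key <- function(m) {
        sort(paste(m[, "donor"], m[, "hydrogen"], m[, "acceptor"]))
      }
      expect_identical(
        key(as.matrix(got[, c("donor", "hydrogen", "acceptor")])),
        key(want)
      )
    }
  }
})

test_that("tightening the criteria never finds more bonds", {
  mm <- make_glycan_mimic(2, 4, 3, TRUE, seed = 8)
  ens <- plant_hbond(mm$ensemble, 0, 2, 7, 3.2, 15)
  base <- nrow(detect_hbonds(ens, 0, hbond_criteria(3.5, 30)))
  expect_lte(nrow(detect_hbonds(ens, 0, hbond_criteria(3.0, 30))), base)
  expect_lte(nrow(detect_hbonds(ens, 0, hbond_criteria(3.5, 20))), base)
})

test_that("occupancy maps count per-pair presence fractions and are symmetric", {
  mm <- make_glycan_mimic(2, 3, 2, FALSE, n_conformers = 50,
    noise_sd = 0, seed = 4)
  ens <- plant_hbond(mm$ensemble, 0, 2, 6, 3.0, 10)
  # wiggle the planted acceptor out of range in 9 of 50 frames:
  # present in 41 of 50 -> occupancy 0.82
  p <- attr(ens, "planted")
  for (f in 42:50) {
    ens$coords[[f]][p$acceptor + 1, ] <-
      ens$coords[[f]][p$acceptor + 1, ] + c(10, 0, 0)
  }
  map <- hbond_occupancy_map(ens, annotation = mm$annotation)
  expect_equal(map$occupancy["2", "6"], 41 / 50)
  expect_identical(map$occupancy, t(map$occupancy))
  expect_equal(map$n_conformers, 50)
  # a pair present in every frame has occupancy 1
  always <- hbond_occupancy_map(
    plant_hbond(mm$ensemble, 0, 2, 6, 3.0, 10),
    annotation = mm$annotation
  )
  expect_equal(always$occupancy["2", "6"], 1)
  # occupancies invariant to rigid-body motion of each conformer
  th <- 0.8
  rot <- matrix(c(
    cos(th), -sin(th), 0,
    sin(th), cos(th), 0, 0, 0, 1
  ), 3, 3, byrow = TRUE)
  moved <- ens
  moved$coords <- lapply(moved$coords, function(x) {
    sweep(x %*% t(rot), 2, c(4, -4, 2), `+`)
  })
  map2 <- hbond_occupancy_map(moved, annotation = mm$annotation)
  expect_equal(map$occupancy, map2$occupancy, tolerance = 1e-10)
})

test_that("category summaries follow the unit labels and sum to 100", {
  mm <- make_glycan_mimic(2, 3, 2, TRUE, seed = 3)
  ann <- mm$annotation
  # plant 3 core->alpha1-6 and 1 core->alpha1-3 bonds per frame
  ens <- mm$ensemble
  ens <- plant_hbond(ens, 0, 2, 7, 3.0, 5)
  ens <- plant_hbond(ens, 0, 3, 8, 3.1, 5)
  ens <- plant_hbond(ens, 0, 1, 7, 3.2, 5) # PA tag counts with the core
  ens <- plant_hbond(ens, 0, 2, 4, 3.0, 5)
  bonds <- detect_hbonds(ens, 0)
  # restrict to the planted pairs (the mimic has incidental contacts)
  planted_pairs <- rbind(c(2, 7), c(3, 8), c(1, 7), c(2, 4))
  keep <- mapply(
    function(d, a) {
      any(planted_pairs[, 1] == d & planted_pairs[, 2] == a)
    },
    bonds$donor_residue, bonds$acceptor_residue
  )
  summ <- categorize_hbonds(bonds[keep, ], ann, n_conformers = 1)
  expect_equal(unname(summ$percent["core-alpha1-6"]), 75)
  expect_equal(unname(summ$percent["core-alpha1-3"]), 25)
  expect_equal(sum(summ$percent), 100, tolerance = 1e-9)
  expect_equal(summ$mean_count, 4)
  # bonds within one arm only -> intra-arm 100
  intra <- data.frame(
    donor = 0, hydrogen = 1, acceptor = 2,
    donor_residue = 4, acceptor_residue = 5,
    distance = 3, angle = 10, conformer = 0
  )
  si <- categorize_hbonds(intra, ann, n_conformers = 1)
  expect_equal(unname(si$percent["intra-arm"]), 100)
  # fucose-involving bonds land in "other" and leave the percentages
  fuc <- intra
  fuc$acceptor_residue <- 9 # fucose residue of the default mimic
  sf <- categorize_hbonds(rbind(intra, fuc), ann, n_conformers = 1)
  expect_equal(sf$n_other, 1)
  expect_equal(sum(sf$percent), 100, tolerance = 1e-9)
  # unannotated residue -> coverage error
  expect_error(
    categorize_hbonds(intra, residue_annotation(1, "PA-tag"),
      n_conformers = 1
    ),
    "does not cover"
  )
})

test_that("globular-vs-rod differences subtract field by field", {
  mm <- make_glycan_mimic(2, 3, 2, TRUE, seed = 3)
  ann <- mm$annotation
  mk <- function(pairs) {
    bonds <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      data.frame(
        donor = 0, hydrogen = 1, acceptor = 2,
        donor_residue = pairs[i, 1], acceptor_residue = pairs[i, 2],
        distance = 3, angle = 10, conformer = 0
      )
    }))
    categorize_hbonds(bonds, ann, n_conformers = 1)
  }
  glob <- mk(rbind(c(2, 4), c(2, 4), c(4, 5))) # 2 core-a13 + 1 intra
  rod <- mk(rbind(c(2, 7), c(2, 4), c(7, 8))) # planted shift to core-a16
  d <- compare_shape_hbonds(glob, rod)
  expect_equal(d$mean_count_diff, 0)
  expect_equal(unname(d$percent_diff["core-alpha1-6"]), -100 / 3)
  expect_equal(unname(d$percent_diff["core-alpha1-3"]), 100 / 3)
  same <- compare_shape_hbonds(glob, glob)
  expect_true(all(unlist(same) == 0))
})
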