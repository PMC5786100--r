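# Ensemble reading, writing and validation.

test_that("multi-model PDB reading preserves model and atom counts", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  coords <- lapply(1:3, function(m) {
    cbind(seq_len(5) * 1.5 + m * 0.1, 0, 0)
  })
  make_test_pdb(tf, coords)
  ens <- read_ensemble(tf, "pdb")
  expect_s3_class(ens, "conformer_ensemble")
  expect_equal(n_conformers(ens), 3)
  expect_equal(nrow(ens$atoms), 5)
  expect_identical(ens$atoms$element, rep(c("C", "O"), length.out = 5))
})

test_that("write/read round trip preserves topology and coordinates", {
  sim <- make_two_state_ensemble(2, 0.5, 4, 0.2, n_atoms = 6, seed = 4)
  ens <- sim$ensemble
  for (fmt in c("pdb", "xyz")) {
    tf <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_ensemble(ens, tf, fmt)
    back <- read_ensemble(tf, fmt)
    expect_equal(n_conformers(back), 2)
    expect_identical(back$atoms$element, ens$atoms$element)
    tol <- if (fmt == "pdb") 5e-4 else 5e-7 # format precision
    for (m in 1:2) {
      expect_lt(max(abs(back$coords[[m]] - ens$coords[[m]])), tol)
    }
  }
  # pdb round trip also keeps residue indices
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, tf, "pdb")
  expect_identical(
    read_ensemble(tf, "pdb")$atoms$residue_index,
    ens$atoms$residue_index
  )
})

test_that("structurally inconsistent inputs are rejected with the model index", {
  # XYZ frame with one atom missing
  tf <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3", "frame 1",
    "C 0 0 0", "C 1 0 0", "C 2 0 0",
    "2", "frame 2",
    "C 0 0 0", "C 1 0 0"
  ), tf)
  expect_error(read_ensemble(tf, "xyz"), "frame 2")
  # PDB model with a short atom count names the offending model
  tfp <- withr::local_tempfile(fileext = ".pdb")
  coords <- lapply(1:2, function(m) cbind(1:4, 0, 0))
  make_test_pdb(tfp, coords)
  lines <- readLines(tfp)
  drop <- max(which(grepl("^ATOM", lines))) # last atom of model 2
  writeLines(lines[-drop], tfp)
  expect_error(read_ensemble(tfp, "pdb"), "model 2")
  # unknown element symbol
  tf2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "f", "Xx 0 0 0"), tf2)
  expect_error(read_ensemble(tf2, "xyz"), "element")
  # empty ensemble refused on write
  sim <- make_two_state_ensemble(1, 1, 2.5, 0, n_atoms = 5, seed = 1)
  broken <- sim$ensemble
  broken$coords <- list()
  expect_error(write_ensemble(broken, tempfile(), "pdb"), "empty")
  # M = 1 ensemble writes a single MODEL/ENDMDL pair
  tf3 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(sim$ensemble, tf3, "pdb")
  lines <- readLines(tf3)
  expect_equal(sum(grepl("^MODEL", lines)), 1)
  expect_equal(sum(grepl("^ENDMDL", lines)), 1)
})

test_that("charge tables attach per-atom charges and enforce coverage", {
  tf <- withr::local_tempfile(fileext = ".csv")
  # placeholder charge set for the default 27-atom glycan mimic
  src <- system.file("extdata", "mimic_charges_2plus.csv",
    package = "glycoccs", mustWork = TRUE
  )
  charges <- read_charge_table(src, n_atoms = 27)
  expect_length(charges, 27)
  # a doubly protonated species carries net +2
  expect_equal(sum(charges), 2, tolerance = 1e-6)
  mm <- make_glycan_mimic(2, 3, 2, TRUE, seed = 1)
  ens <- set_charges(mm$ensemble, charges)
  expect_equal(sum(ens$atoms$charge), 2, tolerance = 1e-6)
  # missing index -> coverage error naming the absent atom
  writeLines(sprintf("%d %.3f", 0:24, charges[1:25]), tf)
  expect_error(read_charge_table(tf, n_atoms = 27), "25")
  # non-numeric charge
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0 0.1", "1 abc"), tf2)
  expect_error(read_charge_table(tf2), "non-numeric")
})

test_that("residue annotations validate labels, ranges and coverage", {
  ann <- read_residue_annotation(lines = c(
    "1-2: core-chitobiose",
    "3-5: alpha1-3-arm",
    "6-8: alpha1-6-arm"
  ))
  expect_s3_class(ann, "residue_annotation")
  expect_equal(unname(ann["4"]), "alpha1-3-arm")
  expect_error(
    read_residue_annotation(lines = c(
      "1-4: core-chitobiose", "4-6: alpha1-3-arm"
    )),
    "more than one"
  )
  expect_error(
    read_residue_annotation(lines = "1-3: antenna"),
    "unknown unit label"
  )
  # coverage check against an ensemble
  mm <- make_glycan_mimic(2, 3, 2, FALSE, seed = 1)
  short <- residue_annotation(1:3, rep("core-chitobiose", 3))
  expect_error(
    hbond_occupancy_map(mm$ensemble, annotation = short),
    "does not cover"
  )
})
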