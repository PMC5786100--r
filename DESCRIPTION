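Package: glycoccs
Title: Gas-Phase Glycan Conformational Ensembles and Collision Cross Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for linking ion-mobility mass spectrometry
    measurements of branched glycans to atomistic conformational ensembles.
    Implements drift-time to collision-cross-section (CCS) calibration with
    polyalanine standards, per-conformer CCS computation by the projection
    approximation and the Lennard-Jones trajectory method in He or N2 buffer
    gas, RMSD-threshold conformational clustering with population-weighted
    CCS distributions, heavy-atom RMSF and gyration-tensor shape
    descriptors, geometric hydrogen-bond network mapping with inter-arm
    category summaries, and experiment-versus-computation comparison
    statistics. Ships synthetic-data generators (calibrant series, mixture
    ensembles with known populations, branched glycan mimics with planted
    hydrogen bonds) that provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
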