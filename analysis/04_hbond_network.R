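#!/usr/bin/env Rscript
# Hydrogen-bond network mapping on branched glycan mimics.
#
# Builds two mimic ensembles with planted inter-unit hydrogen bonds that
# emulate the two folding motifs: a "rod-like" pattern whose alpha1-6 arm
# backfolds onto the core chitobiose, and a "globular" pattern whose
# contacts concentrate on the alpha1-3 arm.  Maps residue-pair occupancy,
# categorizes bonds by structural unit, and differences the two patterns.
# Writes the occupancy matrix and category tables under results/.

library(glycoccs)
dir.create("results", showWarnings = FALSE)
seed <- 20260927

mm <- make_glycan_mimic(2, 3, 2, TRUE, n_conformers = 25, noise_sd = 0.2,
  seed = seed)
ann <- mm$annotation
crit <- hbond_criteria(r_max = 3.5, theta_max = 30)

# rod-like: core -> alpha1-6 backfolding contacts
rod <- mm$ensemble
rod <- plant_hbond(rod, 0, 2, 7, 3.1, 12) # core GlcNAc -> arm16
rod <- plant_hbond(rod, 0, 1, 8, 3.3, 18) # PA tag -> distal arm16
map_rod <- hbond_occupancy_map(rod, crit, ann)
sum_rod <- categorize_hbonds(map_rod, ann)

# globular: contacts fold the alpha1-3 arm over the core
glob <- mm$ensemble
glob <- plant_hbond(glob, 0, 2, 4, 3.1, 12) # core -> arm13
glob <- plant_hbond(glob, 0, 4, 5, 3.2, 15) # within arm13
map_glob <- hbond_occupancy_map(glob, crit, ann)
sum_glob <- categorize_hbonds(map_glob, ann)

cat("rod-like pattern:\n")
print(sum_rod)
cat("globular pattern:\n")
print(sum_glob)

diff <- compare_shape_hbonds(sum_glob, sum_rod)
cat(sprintf(
  "globular - rod: %.2f bonds per conformer; category shifts (%%):\n",
  diff$mean_count_diff
))
print(round(diff$percent_diff, 1))
cat("As in real backfolded glycans, the rod-like pattern is richer in",
  "core/alpha1-6 bonds and the globular one in core/alpha1-3 bonds.\n")

occ <- map_rod$occupancy
write.csv(occ, "results/hbond_occupancy_rod.csv")
write.csv(
  data.frame(
    category = names(sum_rod$percent),
    rod_percent = as.numeric(sum_rod$percent),
    globular_percent = as.numeric(sum_glob$percent),
    globular_minus_rod = as.numeric(diff$percent_diff)
  ),
  "results/hbond_categories.csv",
  row.names = FALSE
)
cat("wrote results/hbond_occupancy_rod.csv, results/hbond_categories.csv\n")
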