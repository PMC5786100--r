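---
title: "Gas-phase glycan ensembles and collision cross sections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas-phase glycan ensembles and collision cross sections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoccs)
```

## The problem

Ion mobility mass spectrometry (IM-MS) separates gas-phase ions by their
momentum-transfer collision cross section (CCS, $\Omega$, in Å²) with a
buffer gas, which reflects molecular size and shape. Branched N-glycans —
oligosaccharides built on a chitobiose core with α1-3 and α1-6 mannose
arms, often pyridylamino (PA) tagged for detection — include isomers of
identical mass whose CCS differs only through conformation. Interpreting
such measurements needs three computational pieces, which this package
provides:

1. **Calibration** from measured drift times to CCS via standards of known
   CCS (doubly protonated polyalanine).
2. **Per-structure CCS engines**: the cheap projection approximation and
   the physical trajectory method, in He or N₂.
3. **Ensemble analysis** that turns a set of conformers into a
   population-weighted CCS distribution, with hydrogen-bond network maps
   and shape descriptors to explain *why* isomers separate.

The package does not run molecular dynamics; it consumes multi-model
PDB/XYZ conformer ensembles from any source, and ships synthetic
generators that stand in for simulation output with known ground truth.

## Calibration model

Drift time $t$ and CCS are related linearly over the calibrated range:
$\mathrm{CCS} = a\,t + b$, fitted by unweighted ordinary least squares on
the calibrant ladder (no per-point uncertainties are available, so no
weighting; no power-law variant is offered because the packaged standards
are explicitly on a linear regime). `fit_calibration()` reports slope,
intercept, $R^2$ and residuals; `apply_calibration()` propagates analyte
drift times at full precision. Rounding to the integer Å² of published
tables happens only at render time.

On the packaged five-point polyalanine ladder the fit is
$\mathrm{CCS} = 41.26\,t + 151.9$ with $R^2 = 0.996$, and nine of the ten
packaged glycan drift times reproduce their published integer CCS. The
exception, G1F(6), computes to 439.48 Å² (rounds to 439, published 440).
This is a defect of the published table, not of the fit: the published
percentage differences for G1F(6) (8.2 with calculated 475; 6.4 with 467)
back-compute to an experimental CCS of ≈439 Å², consistent with our
calibration and inconsistent with the 440 printed next to them. The same
inconsistency propagates to the one-decimal percentage differences and to
the P3-state average (we obtain 7.7, the published value 7.8). We report
the values our computation yields and document the discrepancy rather than
forcing agreement.

## CCS engines

### Projection approximation

`ccs_projection()` estimates the orientation-averaged projected area of
the molecule drawn as hard disks of the per-element combined atom–gas
collision radius. Orientations are uniform random rotations (quaternion
sampling); per-orientation areas come from uniform dart throwing in the
disk-union bounding box; the standard error is over orientations.
Defaults (300 orientations × 4000 darts) put the Monte Carlo error near
0.1% for molecules of tens of atoms.

### Trajectory method

`ccs_trajectory()` computes the temperature-averaged momentum-transfer
collision integral

$$\Omega = \pi b_{\max}^2\,\big\langle 1 - \cos\chi \big\rangle$$

by Monte Carlo over (i) molecular orientation, uniform on rotations, (ii)
impact parameter, area-uniform on $[0, b_{\max}]$, and (iii) relative
speed $g$ with the $\Omega^{(1,1)}$ collision-integral weight
$p(\gamma) \propto \gamma^5 e^{-\gamma^2}$, $\gamma^2 = \mu g^2 / 2k_BT$
(sampled as $\gamma^2 \sim \mathrm{Gamma}(3,1)$). Each gas pseudo-atom
trajectory is integrated classically in the potential

$$V(\mathbf r) = \sum_i 4\varepsilon_i\!\left[\left(\tfrac{\sigma_i}{r_i}\right)^{12}
 - \left(\tfrac{\sigma_i}{r_i}\right)^{6}\right]
 \;-\; \frac{\alpha}{2}\,\Big|\sum_i q_i \hat{\mathbf r}_i / r_i^2\Big|^2$$

(pairwise Lennard-Jones plus the ion–induced-dipole attraction from the
per-atom partial charges $q_i$ and the gas polarizability $\alpha$), and
the scattering angle $\chi$ is the angle between incoming and outgoing
velocities.

Numerical choices, all configurable via `trajectory_params()`:

* **Sampling structure.** Published trajectory-method protocols specify
  "25 integration points" for the Monte Carlo integration of impact
  factor and orientation without defining the loop structure. Here one
  *cycle* is 25 (orientation, $b$, $g$) samples; cycles repeat until the
  standard error over cycle means drops below 1% of the running mean or a
  cycle cap binds. The standard error is honest (over cycles) either way.
* **Integrator.** Cash–Karp Runge–Kutta 4(5) with adaptive steps (local
  tolerance `error_tol = 1e-10`); each trajectory's total-energy drift is
  checked and the trajectory re-integrated with 100× tighter control if
  relative drift exceeds `energy_tol = 1e-6`. Observed drifts are ~1e-10.
* **Geometry.** Coordinates are centered; $b_{\max}$ = radial extent +
  $\sigma_{\max}$ + 10 Å, start distance adds 15 Å, in the spirit of
  MOBCAL's asymptotic criterion. Trajectories that exhaust the step
  budget (orbiting resonances) are resampled and counted; >1% triggers a
  recorded warning.
* **Gas model.** N₂ is a single isotropic pseudo-atom with the N₂ mass
  and polarizability (1.7403 ų) and effective per-element LJ parameters
  — a deliberate simplification of four-site diatomic N₂ models. The
  parameter file (`inst/extdata/gas_params.yaml`) documents provenance
  and can be replaced wholesale (`gas_model(params_file=)`).
* **Charges.** Absent charges default to zero with a warning (the
  induced-dipole term vanishes); a two-column sidecar
  (`read_charge_table()` + `set_charges()`) attaches real charge sets.
  The packaged `mimic_charges_2plus.csv` is a synthetic placeholder for a
  doubly protonated species (net +2); calculated CCS for real glycans
  depends on force-field charge sets that are not redistributable here,
  so per-glycan trajectory CCS values are illustrative, not reference
  values.

The test suite verifies the engines against independent oracles: analytic
disk area, a dense-grid rasterization of the projected union, a
finite-difference gradient check of the force, the classical
deflection-angle quadrature for single-center scattering, and a full 2-D
$(g, b)$ quadrature of the collision integral.

## Ensemble analysis

### Clustering

`cluster_ensemble()` implements a deterministic radius-limited k-means:
all conformers are Kabsch-superposed to the first conformer on heavy
atoms, k-means runs on the flattened coordinates, and the cluster whose
members stray farthest from their centroid is split — seeding the two new
centroids at its two most distant members — until every member lies
within the RMSD threshold of its centroid. Thresholds follow common
practice for conformer families: 2.5 Å for coarse clusters, 0.5 Å for the
fine distribution (capped at 2,625 clusters, with a warning if the cap
binds). The cluster representative is the **medoid** (the member with
minimal mean RMSD to co-members), not the coordinate centroid, because a
physical structure is required for CCS computation. Superposing to a
single reference rather than all pairs is a documented simplification;
for the well-separated mixtures the generators produce, the partition is
identical either way.

### Population weighting, RMSF, shape

`weighted_ccs_distribution()` weights each medoid CCS by its cluster's
population fraction, yielding support points, a histogram (default 5 Å²
bins) and the weighted mean. `rmsf()` superposes all conformers to the
iteratively refined mean structure (tolerance 1e-6 Å) and reports
per-atom heavy-atom fluctuations. `shape_descriptor()` computes the
gyration tensor, its sorted eigenvalues and the relative shape anisotropy
$\kappa^2 \in [0, 1]$; the globular/rod-like call uses a $\kappa^2$
threshold of 0.4, a package convention chosen near the midpoint of the
two limits (published classifications of glycan folds are visual, so no
literature cutoff exists).

## Hydrogen-bond networks

`detect_hbonds()` uses the donor-centered geometric criterion: donor
heavy atom X (N or O) bearing hydrogen H, acceptor heavy atom Y, with
$R_{XY} < 3.5$ Å and $\theta_{HXY} < 30°$, where $\theta_{HXY}$ is the
angle between the X–H bond vector and the X–Y vector. The common
alternative (the X–H⋯Y angle at the hydrogen) is deliberately **not**
used. Hydrogens attach to their nearest donor-element heavy atom within
1.2 Å; intra-residue pairs are excluded by default. Occupancy of a
residue pair is the fraction of conformers with ≥1 bond between them
(multiplicity is available separately as a per-pair mean count).

`categorize_hbonds()` pools bonds across conformers — rather than
averaging per-frame percentages, a documented choice — and assigns each
to core–α1-6, core–α1-3, α1-3–α1-6 or intra-arm from the residue unit
labels; the PA tag counts with the core, and fucose-involving bonds fall
outside the four-way percentages into "other".

## Synthetic generators: what they do and do not show

The generators provide every fixture with full ground truth:

* `make_calibrants()` — drift/CCS points on a known line with Gaussian
  noise.
* `make_two_state_ensemble()` — mixtures of two rigid bead-chain
  conformations at an exact best-fit RMSD separation (a hinge angle
  solved by bisection, realized within 5%), with labels drawn first and
  per-atom noise second so the draw is reproducible from the seed.
* `make_glycan_mimic()` — a branched bead-residue topology (PA tag, core,
  two arms, optional fucose) of rigid C/O/H groups, self-avoiding at
  1.5 Å, with the five-unit annotation.
* `plant_hbond()` — inserts an O–H donor and O acceptor at an exact
  (R, θ) geometry outside the molecule.

Defaults mirror the study conditions the analysis targets: 60/40 mixture
weights, 10 Å state separation, 0.1 Å thermal jitter, 200-frame
ensembles, 2.5/0.5 Å thresholds. What passing tests on these fixtures
demonstrates is that the *operators* are correct: populations are
recovered, planted geometries are detected exactly at the criterion
boundary, and engines match quadrature oracles. What they cannot show is
fidelity to real carbohydrate ensembles: bead mimics have no sugar
stereochemistry, no force field, and no conformational free-energy
surface, and real trajectory ensembles (2,500-snapshot REMD output) are
not deposited, so published per-glycan calculated CCS values and
real-map H-bond occupancies (e.g. 82%/52% inter-arm contacts) are out of
reach by construction.

## Problem sizes and determinism

The packaged demo and test suite run at deliberately modest sizes chosen
to keep the full analysis reproducible on a laptop: 200-frame mixtures,
≤200-atom H-bond fixtures, 200 Monte Carlo orientations for projection,
and 25-point × ≤200-cycle trajectory runs (3,000–5,000 trajectories,
standard error ≈10%). Every stochastic routine takes an explicit integer
seed, derives per-conformer seeds as `seed + 1000003 × (index+1)` so
results are independent of request order, and restores the caller's RNG
state. `run_pipeline()` on a fixed config + seed reproduces its JSON
report byte for byte.

## Known limitations

* The G1F(6) inconsistency in the published comparison table (above).
* Single-site N₂: quadrupole and anisotropic repulsion of the diatomic
  are folded into effective LJ parameters; absolute N₂ CCS values carry
  that systematic.
* No exact-hard-sphere-scattering (EHSS) engine, no diffuse-scattering
  model, no traveling-wave power-law calibration.
* Radius-limited k-means guarantees the radius criterion, not a global
  optimum; with overlapping states (separation below ~4× threshold or
  noise above ~threshold/5) cluster counts can exceed the state count.
* H-bond detection requires explicit hydrogens; structures without them
  raise an error rather than guessing positions.
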