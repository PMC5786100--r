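# Packaged demo: calibration on the polyalanine ladder, a two-state
# synthetic ensemble through clustering and projection CCS, a glycan-mimic
# hydrogen-bond network with planted geometries, and the published-table
# comparison statistics.
seed: 7
calibration:
  calibrants: polyalanine_calibrants.csv
  analytes: glycan_drift_times.csv
ensemble:
  n_frames: 60
  weight_a: 0.6
  rmsd_separation: 10
  noise_sd: 0.1
  threshold: 2.5
  gas: He
  n_orientations: 60
  n_darts: 1000
hbonds:
  core_length: 2
  arm13_length: 3
  arm16_length: 2
  fucose: true
  r_max: 3.5
  theta_max: 30
  plant:
    - {donor_residue: 2, acceptor_residue: 6, r: 3.0, theta: 10.0}
comparison:
  table: glycan_ccs_comparison.csv
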