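# Demo configuration for the end-to-end circuit-mapping pipeline.
# Reruns with the same master_seed reproduce every output hash exactly.
master_seed: 17
output_dir: perturbcircuit_demo
sim:
  n_genes: 2000
  n_targets: 6
  n_guides_per_target: 3
  n_programs: 8
  genes_per_program: 40
  cells_per_guide: 120
  n_control_cells: 360
  doublet_rate: 0.05
qc:
  min_genes: 200
  min_counts: 1000
  max_mito: 0.20
clinical:
  program: P-0
  n_samples: 300
  hr_per_unit: 0.5
  n_perm: 200
  r_target: -0.35
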