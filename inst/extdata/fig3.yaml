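seed: 1
out_dir: fig3_run
model:
  baseline_penetrance: 0.01
power:
  or_grid: [2, 3, 5]
  n_variants: [3, 5, 9]
  maf: 0.01
  n_pairs: 2658
  alpha_linkage: 1.0e-4
  n_cases: 3000
  n_controls: 3000
  alpha_gwas: 5.0e-8
  reps: 100
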