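seed: 1
out_dir: nod2_run
model:
  preset: nod2
  baseline_penetrance: 0.01
pool:
  n_common: 20
  freq_min: 0.1
  freq_max: 0.5
  region_length: 200000
cohort:
  design: case_control
  n_cases: 2000
  n_controls: 3000
scan:
  condition: true
  mode: compound
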