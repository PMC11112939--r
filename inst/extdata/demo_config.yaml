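version: 1
seed: 7.0
out_dir: nics_run
simulation:
  n_embryos: 50.0
  depth: 2000000.0
  dispersion: 0.05
  gc_bias_strength: 4.0
  n_reference: 8.0
cbs:
  alpha: 0.01
  n_perm: 1000.0
  min_bins: 3.0
  undo_sd: 1.0
calling:
  call_margin: 0.3
  min_size_mb: 10.0
features:
  redefine_threshold: 0.5
  full_threshold: 0.8
grading:
  grade_a: 0.94
  grade_c: 0.7
  n_trees: 500.0
  mtry: 3.0
  n_training: 1500.0
  training_noise_sd: 0.04
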