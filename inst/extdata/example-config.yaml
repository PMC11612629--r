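# Example pipeline configuration for the `eegswarm run` CLI subcommand.
# A single master seed reproduces the whole run.
source: synthetic
n_per_class: 20
seed: 1
window_len: 1024
overlap: 64
fractions: [0.9, 0.05, 0.05]
models: [rf]
ablation: full_pmpso
cv_folds: 10
out_dir: eegswarm_run
filter:
  band_low: 0.5
  band_high: 70
  order: 4
  notch_freq: 50
  notch_q: 30
extraction:
  wavelet: db4
  n_levels: 5
  rat_mode: cyclic
  welch_M: 256
pmpso:
  n_particles: 30
  max_iters: 50
  c1: 2.05
  c2: 2.05
  top_k: 10
  delta: 0.6
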