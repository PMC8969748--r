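# End-to-end smoke run at reduced scale: synthetic audiogram + synthetic
# speech-surrogate stimuli + envelope-correlation proxy scorer,
# 4 threads x 50 iterations (the full-scale run uses 1000 iterations).
audiogram:
  synthetic: {severity: moderately_severe, seed: 7}
ha:
  ig65_db: [15, 20, 25, 25, 20]
  ig85_db: [5, 10, 12, 12, 8]
  ct_db_spl: [45, 45, 50, 50, 50]
search:
  n_iterations: 50
  n_threads: 4
  seeds: [1, 2, 3, 4]
scorer: {type: proxy}
stimuli: {type: synthetic, n_items: 3, duration_s: 0.6, level_db_spl: 65, seed: 1}
output_dir: hafit_smoke_out
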