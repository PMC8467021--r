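# Example anopeak run configuration (simulate mode).
# Real-data mode instead takes: peaks_bed, crms_bed, cell_line,
# crumb_enabled: yes, and usually a lower learning_rate (1e-4).
out_dir: anopeak_out
seed: 1
simulate:
  count: 3000
  m: 8
  n: 8
  watermark_prob: 0.75
  removal_prob: 0.25
  jitter_bound: 200
  length_median: 250
  length_shape: 0.25
  region_bp: 3200
model:
  kernel_len: 20
  conv_filters: 16
  deep_dim: 32
  learning_rate: 1e-3
  kernel_reg: 0
  batch_size: 48
  batches_per_epoch: 10
  patience: 5
  min_delta: 2.5e-4
  max_epochs: 48
mc_sample_size: 10000
normalize: yes
run_qscore: yes
run_interpret: yes
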