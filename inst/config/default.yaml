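# Full study-scale run: 24 subjects x 2 tasks, 300-s sessions at 128
# samples/s, 12,000 encoded images, 20/2/2 subject split.
cohort:
  n_subjects: 24
  fs: 128
  seed: 1
preprocess:
  highpass_cutoff: 1
  lowpass_cutoff: 50
  filter_order: 5
connectivity:
  max_lag: 0
encoder:
  analysis_subtasks: [KATA-III, Plan]
soft_sensor:
  dense_units: 128
  learning_rate: 0.001
  epochs: 10
  batch_size: 32
  seed: 1
  split_seed: 1
output_dir: eegkata-run
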