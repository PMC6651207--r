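# 4-subject smoke run for quick end-to-end checks.
cohort:
  n_subjects: 4
  fs: 128
  seed: 1
soft_sensor:
  epochs: 2
  seed: 1
  split_seed: 1
output_dir: eegkata-smoke
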