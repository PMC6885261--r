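# Default wpemg pipeline configuration: 3 x 17 five-second recordings at
# 20 kHz, level-4 db4 wavelet-packet features over 2048-sample frames,
# AdaBoost.M1 over a 25-tree random forest, stratified 10-fold CV.
seed: 42
output_dir: wpemg_output
log_level: info
simulate:
  n_recordings_per_class: 17
  sampling_rate_hz: 20000
  duration_s: 5
  bandpass_low_hz: 5
  bandpass_high_hz: 10000
wpd:
  wavelet_name: db4
  level: 4
  frame_length: 2048
  overlap: 0
learner:
  name: random_forest
  n_trees: 25
ensemble:
  method: adaboost
  T: 10
cv:
  k_folds: 10
  grouping: frame
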