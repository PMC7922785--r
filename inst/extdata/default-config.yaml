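cuts:
  sed_lpa: 44.8
  lpa_mvpa: 100.6
  source_label: hildebrand-adult-nondominant-wrist
met_breakpoints:
- 1.5
- 3.0
- 6.0
choi_window: 90.0
choi_spike_tol: 2.0
choi_spike_win: 30.0
epoch_s: 60.0
coverage_min: 0.5
epoch_missing_tol: 0.0
stillness_floor: 1.0
calib_sd_thresh: 0.013
calib_min_windows: 10.0
valid_day_min: 0.0
ci_level: 0.9
ez_granularity: 0.1
seed: 1
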