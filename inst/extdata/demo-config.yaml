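# Demo pipeline configuration: a single-channel microcolony with an
# 8-step activation chain (mean 4 h), imaged every 15 min.
seed: 1
simulate:
  n_founders: 4
  growth_rate_mean: 0.2
  frame_interval: 0.25
  pre_stress_duration: 1
  post_stress_duration: 10
  chain:
    n_steps: 8
    mean_time: 4
  reporters:
    yfp:
      production_rate: 1000
      noise_sd: 0.5
preprocess:
  background_mode: per_frame
respond:
  measure: threshold
stats:
  n_subsamples: 200
  n_bootstrap: 200
  n_permutations: 500
kinetics:
  n_sim: 200
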