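{
  "seed": 0,
  "nucleation": {
    "doses_nM": [0, 3.75, 7.5, 15, 30, 60],
    "strength_au_per_s_per_nM": 0.32,
    "baseline_slope_au_per_s": 0.1
  },
  "capping": {
    "kd_nM": 0.028,
    "a": 1,
    "b": -4.5,
    "barbed_ends_nM": 0.1,
    "doses_nM": [0, 0.0028, 0.0056, 0.0112, 0.0224, 0.0448, 0.0896, 0.1792, 0.3584, 0.7168, 1.4336, 2.8672],
    "noise_sd": 0
  },
  "tirf": {
    "n_filaments": 8,
    "duration": 600
  },
  "bundling": {
    "doses_nM": [0, 3.75, 7.5, 15, 30, 60],
    "true_fractions": [0.05, 0.15, 0.35, 0.55, 0.72, 0.817],
    "noise_cv": 0.05,
    "n_replicates": 3
  }
}
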