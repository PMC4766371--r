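{
  "exp1": {
    "w_within": 0.9, "w_cross": 0.0, "alpha": 0.5,
    "tau": 1.5, "lapse": 0.1
  },
  "exp2_visual": {
    "w_within": 0.9, "w_cross": 0.0, "alpha": 0.5,
    "tau": 1.5, "lapse": 0.1
  },
  "exp2_auditory": {
    "w_within": 0.9, "w_cross": 0.0, "alpha": 0.5,
    "tau": 0.8, "lapse": 0.1
  },
  "null": {
    "w_within": 0.0, "w_cross": 0.0, "alpha": 0.5,
    "tau": 1.0, "lapse": 0.0
  }
}
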