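{
  "exp1": {
    "A": ["tone_210Hz", "tone_286Hz", "tone_389Hz"],
    "V": ["shape_1", "shape_2", "shape_3"]
  },
  "exp2_visual": {
    "A": ["color_red", "color_green", "color_blue"],
    "V": ["shape_1", "shape_2", "shape_3"]
  },
  "exp2_auditory": {
    "A": ["tone_210Hz", "tone_286Hz", "tone_389Hz"],
    "V": ["nonword_dak", "nonword_pel", "nonword_vot"]
  }
}
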