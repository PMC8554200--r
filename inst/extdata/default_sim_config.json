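{
  "n_pairs": 45,
  "n_markers": 1000,
  "causal_marker_A": 500,
  "causal_marker_B": 500,
  "allele_freq": 0.5,
  "times": [0, 2.4, 4.8, 7.2, 9.6, 12, 14.4, 16.8, 19.2, 21.6, 24, 26.4, 28.8, 31.2, 33.6, 36],
  "h2": 0.1,
  "step": 0.01,
  "base_theta": {
    "r_e": 0.5, "K_e": 23.94, "alpha_es": -0.01,
    "r_s": 0.4, "K_s": 21.56, "alpha_se": -0.02
  },
  "init": { "E0": 0.5, "S0": 0.5 },
  "effects": {
    "A_r_e": 0.08, "A_K_e": 0.06, "A_alpha_se": 0.6,
    "B_r_s": 0.08, "B_K_s": 0.06, "B_alpha_es": 0.6
  },
  "sad": { "phi_e": 0.75, "phi_s": 0.75, "nu_e": 1, "nu_s": 1, "rho": 0.3 },
  "include_monoculture": true
}
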