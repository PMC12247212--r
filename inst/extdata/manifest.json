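{
  "synthetic_nanobody": {
    "file": "synthetic_nanobody.csv",
    "k_on": 230000,
    "k_off": 0.0112,
    "R_max": 0.14,
    "K_D": 4.8695652173913e-08,
    "sigma": 0.005,
    "drift": 0,
    "step_shift_sd": 0,
    "seed": 2026
  }
}
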