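steps:
- kind: ASSOCIATION
  duration_s: 300.0
  concentration_nM: 25.00000000000000355
  label: well 1
- kind: MINI_DISSOCIATION
  duration_s: 30.0
- kind: ASSOCIATION
  duration_s: 250.0
  concentration_nM: 50.00000000000000711
  label: well 2
- kind: MINI_DISSOCIATION
  duration_s: 30.0
- kind: ASSOCIATION
  duration_s: 200.0
  concentration_nM: 100.00000000000001421
  label: well 3
- kind: MINI_DISSOCIATION
  duration_s: 30.0
- kind: ASSOCIATION
  duration_s: 150.0
  concentration_nM: 200.00000000000002842
  label: well 4
- kind: MINI_DISSOCIATION
  duration_s: 30.0
- kind: ASSOCIATION
  duration_s: 100.0
  concentration_nM: 400.00000000000005684
  label: well 5
- kind: FINAL_DISSOCIATION
  duration_s: 600.0
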