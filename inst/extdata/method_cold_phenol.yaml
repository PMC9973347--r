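name: cold_phenol
e0: 0.3
size_bias:
  l50: 300.0
  width: 60.0
  floor: 0.05
state_factor:
  plateau: 0.35
  rate: 0.04
  min_length: 0.0
fragment_recovery: 0.0
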