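format: spkmix/1
epsilon: 1.0
genes:
- id: X
  binding_sites:
  - Yc
  alpha:
  - 0.005
  alpha_off:
  - 1.0
  production:
    '0': 40.0
    '1': 0.0
  decay: 1.0
  cooperativity: 2
  beta: 1.0
  beta_off: 1.0
- id: 'Y'
  binding_sites:
  - Xc
  alpha:
  - 0.005
  alpha_off:
  - 1.0
  production:
    '0': 40.0
    '1': 0.0
  decay: 1.0
  cooperativity: 2
  beta: 1.0
  beta_off: 1.0
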