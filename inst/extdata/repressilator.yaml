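format: spkmix/1
epsilon: 0.1
genes:
- id: X
  binding_sites:
  - 'Y'
  alpha:
  - 5.0
  alpha_off:
  - 1.0
  production:
    '0': 2000.0
    '1': 0.0
  decay: 20.0
  cooperativity: 1
- id: 'Y'
  binding_sites:
  - Z
  alpha:
  - 5.0
  alpha_off:
  - 1.0
  production:
    '0': 2000.0
    '1': 0.0
  decay: 20.0
  cooperativity: 1
- id: Z
  binding_sites:
  - X
  alpha:
  - 5.0
  alpha_off:
  - 1.0
  production:
    '0': 2000.0
    '1': 0.0
  decay: 20.0
  cooperativity: 1
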