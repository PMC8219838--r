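seed: 1
stimulus:
  directions:
  - L_plus_M
  - L_minus_M
  frequencies:
  - 1.0
  - 2.0
  - 5.0
  - 10.0
  - 20.0
  duration: 0.666
  ramp: 0.166
  eccentricity: 5.0
  aperture_sigma: 0.4
tcsf: ~
behavior:
  pc: 0.82
  criterion: ~
neurons:
  n_magno: 4.0
  n_parvo: 4.0
  latency: 0.1
  surround_delay: 0.01
trials:
  n_per_condition: 40.0
  dt: 0.001
  pad: 0.3
snr:
  bootstrap_B: 500.0
  sweep_offsets:
  - 0.0
  - 0.04
  - 0.08
  - 0.12
  - 0.16
  - 0.2
population: ~
cones: ~
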