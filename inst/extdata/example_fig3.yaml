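# Dose-response setting: linear, decreasing, increasing, saturation regimes
model:
  alpha: 1
  beta: 5.0e+2
  gamma: 1.2e-6
  phi: 9.0e-2
  b: 4.0e-2
  kappa: 1.0e-4
  nu1: 1.0e-2
  nu2: 0
  L1: 1
  L2: 0
  R: 3.0e+4
  ST: 6.0e+5
  "N": 3
response:
  l1_from: 1.0e-2
  l1_to: 1.0e+8
  "n": 120
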