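# Worked example with three positive steady states (N = 3, agonist only)
model:
  alpha: 1
  beta: 1
  gamma: 1
  phi: 1
  b: 0
  kappa: 2.0e-4
  nu1: 1.0e-4
  nu2: 0
  L1: 1
  L2: 0
  R: 1
  ST: 10
  "N": 3
steady_states: true
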