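# Ligand-sweep setting (fold bifurcation in L1); note nu1 = 1 here,
# unlike the three-steady-state worked example (nu1 = 1e-4).
model:
  alpha: 1
  beta: 1
  gamma: 1
  phi: 1
  b: 0
  kappa: 2.0e-4
  nu1: 1
  nu2: 0
  L1: 1
  L2: 0
  R: 1
  ST: 10
  "N": 3
steady_states: true
scan:
  name: L1
  from: 1.0e-4
  to: 10
  "n": 60
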