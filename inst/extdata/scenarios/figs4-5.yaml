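# Supercritical perturbation: beta1 raised to 0.6 so that R0 > 1
name: figs4-5
params:
  Lambda: 159.5
  nu: 0.1595
  beta1: 0.6
  beta2: 1.0e-05
  psi: 0.3
  phi: 0.7
  theta1: 0.03
  theta2: 0.02
  theta3: 0.3
  gamma1: 3.84615384615384629e-05
  gamma2: 0.001
  gamma3: 0.001
  delta1: 0.035
  delta2: 0.3
  delta3: 0.002
  delta4: 0.001
vartheta: [0.85, 0.90, 0.95, 1.0]
zeta: [1.0]
multipliers: [1.0]
t_end: 400
n_steps: 4000
solver: caputo
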