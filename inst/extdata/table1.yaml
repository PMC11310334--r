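Lambda: 159.5
nu: 0.1595
beta1: 0.40000000000000002
beta2: 1.00000000000000008e-05
psi: 0.29999999999999999
phi: 0.69999999999999996
theta1: 0.03
theta2: 0.02
theta3: 0.29999999999999999
gamma1: 3.84615384615384629e-05
gamma2: 0.001
gamma3: 0.001
delta1: 0.035
delta2: 0.29999999999999999
delta3: 0.002
delta4: 0.001
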