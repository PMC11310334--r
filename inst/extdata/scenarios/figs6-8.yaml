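# Contact-rate reduction study: baseline rates cut by 25/50/75%
name: figs6-8
vartheta: [1.0, 0.88]
zeta: [1.0]
multipliers: [1.0, 0.75, 0.5, 0.25]
apply_to: [beta1, beta2]
t_end: 100
n_steps: 1000
solver: fractal_fractional
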