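# Subcritical baseline: Caputo solver, four fractional orders, R0 < 1
name: figs2-3
vartheta: [0.85, 0.90, 0.95, 1.0]
zeta: [1.0]
multipliers: [1.0]
t_end: 400
n_steps: 4000
solver: caputo
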