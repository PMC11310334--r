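# Fractal-fractional subcritical study: the union of the three order grids
# (zeta fixed at 1; vartheta fixed at 1; both varied jointly)
name: figs9-11
orders:
  - {vartheta: 0.85, zeta: 1.0}
  - {vartheta: 0.90, zeta: 1.0}
  - {vartheta: 0.95, zeta: 1.0}
  - {vartheta: 1.0,  zeta: 1.0}
  - {vartheta: 1.0,  zeta: 0.80}
  - {vartheta: 1.0,  zeta: 0.90}
  - {vartheta: 1.0,  zeta: 0.95}
  - {vartheta: 0.95, zeta: 0.90}
  - {vartheta: 0.90, zeta: 0.70}
  - {vartheta: 0.85, zeta: 0.80}
multipliers: [1.0]
t_end: 400
n_steps: 4000
solver: fractal_fractional
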