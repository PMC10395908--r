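# Two-bound-state optimum at physiological -dG_ATP/kBT = 25 with stiffness
# cap kappa/2 = 40. Published values: v = 0.406 (in k_ATP*d units),
# G2 = -22.3 kBT, attachment rate 4.12. The bound-bound transition is fast
# (thermally equilibrated), so its bare rate and load-distribution
# coefficient are representative fill-ins (1e8, 0.5) that do not affect the
# observables; the detachment rate is the rate unit.
meta:
  schema_version: 1
  reference_velocity: 0.406
cycle:
  n_bound: 2
  G: [0.0, 0.0, -22.3, -25.0]
  d: [1.0, 1.0, 0.0, 0.0]
  alpha: [1.0, 0.5, 0.0, 0.0]
  k0: [4.12, 1.0e8, 1.0]
  dG_ATP: -25.0
  k_hyd: 10000.0
potential:
  kind: harmonic
  half_kappa: 40.0
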