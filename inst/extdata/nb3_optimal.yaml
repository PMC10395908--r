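# Three-bound-state optimum at -dG_ATP/kBT = 25, kappa/2 = 40 (free
# velocity). Published values: G2 = -24.8, G3 = -12.8 (uphill ADP
# release), d2 = 0.119, and v = 0.147 in units of the attachment rate times
# the stroke. The attachment rate itself is not printed; it is set to 1 here
# (a representative value), making the reference velocity 0.147 in attach
# rate units. Bound-bound rates are fast equilibrated fill-ins.
meta:
  schema_version: 1
  reference_velocity: 0.147
cycle:
  n_bound: 3
  G: [0.0, 0.0, -24.8, -12.8, -25.0]
  d: [1.0, 1.0, 0.119, 0.0, 0.0]
  alpha: [1.0, 0.5, 0.5, 0.0, 0.0]
  k0: [1.0, 1.0e8, 1.0e8, 1.0]
  dG_ATP: -25.0
  k_hyd: 10000.0
potential:
  kind: harmonic
  half_kappa: 40.0
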