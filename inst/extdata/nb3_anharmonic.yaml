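# Anharmonic variant of the rate-capped three-state optimum: the elastic
# element is stiff (curvature at the cap, kappa = 48) for x >= x_a and
# perfectly compliant below, with published transition point x_a = -0.19.
# Published values: G2 = -16.8, G3 = -23.2, d2 = 0.24, alpha2 = 0,
# attachment rate 1.91. Unprinted quantities filled in as in the harmonic
# fixed-velocity fixture.
meta:
  schema_version: 1
  reference_velocity: 0.3
cycle:
  n_bound: 3
  G: [0.0, 0.0, -16.8, -23.2, -25.0]
  d: [1.0, 1.0, 0.24, 0.0, 0.0]
  alpha: [1.0, 0.5, 0.0, 0.0, 0.0]
  k0: [1.91, 1.0e8, 6.01, 1.0]
  dG_ATP: -25.0
  k_hyd: 10000.0
potential:
  kind: two_regime
  half_kappa: 24.0
  x_a: -0.19
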