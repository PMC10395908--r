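# Three-bound-state optimum at a prescribed velocity with rate caps (ATP
# detachment rate = 1 = rate unit; ADP binding capped at 1/100) and
# stiffness cap kappa/2 = 24. Published values: G2 = -15.1,
# G3 = -22.3, d2 = 0.25, alpha2 = 0, attachment rate 2.33. The ADP-release
# rate sits at its indirect cap (ADP binding = 0.01 via detailed balance:
# k = 0.01 * exp(G2 - G3) = 0.01 * exp(7.2)). The bound-bound stroke rate
# and alpha1, and the velocity itself, are not printed; the velocity is a
# representative mid-range value.
meta:
  schema_version: 1
  reference_velocity: 0.1
cycle:
  n_bound: 3
  G: [0.0, 0.0, -15.1, -22.3, -25.0]
  d: [1.0, 1.0, 0.25, 0.0, 0.0]
  alpha: [1.0, 0.5, 0.0, 0.0, 0.0]
  k0: [2.33, 1.0e8, 13.39, 1.0]
  dG_ATP: -25.0
  k_hyd: 10000.0
potential:
  kind: harmonic
  half_kappa: 24.0
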