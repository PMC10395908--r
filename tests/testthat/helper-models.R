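# Shared model builders for the test suite. Everything is generated in code;
# no stored fixtures beyond the packaged YAML parameter sets.

# Two-bound-state cycle at the published optimum (fast bound-bound step).
nb2_cycle <- function(k_hyd = 1e5, k1 = 1e8, alpha1 = 0.5)
  motor_cycle(2, G = c(0, 0, -22.3, -25), d = c(1, 1, 0, 0),
              alpha = c(1, alpha1, 0, 0), k0 = c(4.12, k1, 1),
              dG_ATP = -25, k_hyd = k_hyd)

nb2_pot <- function() elastic_potential("harmonic", kappa = 80)

# Gentle moderate-stiffness model with a monotone force-velocity relation
# (no hysteresis): the honest regime for ensemble-vs-stationary comparison.
gentle_cycle <- function(k_hyd = 20)
  motor_cycle(2, G = c(0, 0, -14, -25), d = c(1, 1, 0, 0),
              alpha = c(1, 0.5, 0, 0), k0 = c(3, 50, 1), dG_ATP = -25,
              k_hyd = k_hyd)

gentle_pot <- function() elastic_potential("harmonic", kappa = 10)

# Soft-spring, near-irreversible cycle matching the analytic limit: forward
# free-energy drops of at least 5 kBT per step, fast first transition.
soft_cycle <- function(k_hyd = 1e5)
  motor_cycle(2, G = c(0, -5, -15, -25), d = c(1, 1, 0, 0),
              alpha = c(1, 0.5, 0, 0), k0 = c(4, 400, 1), dG_ATP = -25,
              k_hyd = k_hyd)

soft_pot <- function() elastic_potential("harmonic", kappa = 0.5)

# Seeded random moderate cycles for property tests.
random_cycle <- function(nb = sample(2:3, 1)) {
  ns <- nb + 2L
  G <- c(0, 0, sort(runif(nb - 1, -20, -2), decreasing = TRUE), -25)
  G <- G[seq_len(ns)]
  G[ns] <- -25
  d <- c(1, 1, if (nb > 2) sort(runif(nb - 2, 0.1, 0.9), decreasing = TRUE),
         0, 0)
  alpha <- c(1, runif(nb - 1), 0, 0)
  k0 <- c(exp(runif(nb, log(0.5), log(20))), 1)
  motor_cycle(nb, G = G, d = d, alpha = alpha, k0 = k0, dG_ATP = -25)
}

random_pot <- function() elastic_potential("harmonic", kappa = runif(1, 5, 30))
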