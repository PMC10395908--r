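test_that("mechanical equilibration balances bound heads against the load", {
  harm <- elastic_potential("harmonic", kappa = 80)
  # one bound harmonic motor at zero strain under load f: delta = f / kappa
  expect_equal(mechanical_equilibrate(0, harm, 8), 8 / 80, tolerance = 1e-10)
  # two motors at strains +-a, zero load: no shift
  expect_equal(mechanical_equilibrate(c(-0.3, 0.3), harm, 0), 0,
               tolerance = 1e-10)
  # two-regime potential with mixed-regime strains vs a bisection oracle
  tr <- elastic_potential("two_regime", kappa = 48, x_a = -0.19)
  strains <- c(-0.8, -0.05, 0.4, 1.1)
  f_load <- 10
  delta <- mechanical_equilibrate(strains, tr, f_load)
  oracle <- function() {
    lo <- -5; hi <- 5
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (sum(potential_force(tr, strains + mid)) >= f_load) hi <- mid
      else lo <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(delta, oracle(), tolerance = 1e-10)
  expect_equal(sum(potential_force(tr, strains + delta)), f_load,
               tolerance = 1e-8)
  # no bound motors: defined error for the caller
  expect_error(mechanical_equilibrate(numeric(0), harm, 1),
               class = "motorlimits_no_bound_error")
})

test_that("ensemble traces are reproducible and conserve the bookkeeping", {
  cyc <- gentle_cycle()
  pot <- gentle_pot()
  tr1 <- simulate_ensemble(cyc, pot, 20, F_load = 10, t_end = 50, seed = 5)
  tr2 <- simulate_ensemble(cyc, pot, 20, F_load = 10, t_end = 50, seed = 5)
  expect_identical(tr1$events, tr2$events)
  tr3 <- simulate_ensemble(cyc, pot, 20, F_load = 10, t_end = 50, seed = 6)
  expect_false(identical(tr3$events, tr1$events))
  ev <- tr1$events
  expect_true(all(diff(ev$time) >= 0))
  expect_true(all(ev$bound >= 0 & ev$bound <= 20))
  # unloaded ensemble: no work, zero efficiency, forward progress
  tr0 <- simulate_ensemble(cyc, pot, 20, F_load = 0, t_end = 100, seed = 5)
  s0 <- trace_summary(tr0)
  expect_equal(s0$work, 0)
  expect_equal(s0$efficiency, 0)
  expect_gt(s0$velocity, 0)
  # a trace uses energy: work never exceeds the free energy consumed
  s1 <- trace_summary(tr1)
  expect_lte(s1$work, s1$n_ATP * 25)
})

test_that("a deterministic synthetic trace yields its exact slope", {
  tt <- seq(0, 100, by = 0.5)
  tr <- structure(list(
    events = data.frame(time = tt, X = 5 - 0.37 * tt,
                        n_ATP = round(seq(0, 300, length.out = length(tt))),
                        bound = 10),
    config = list(cycle = gentle_cycle(), n_motors = 10, F_load = 2,
                  t_end = 100, burn_in = 0.1, thin = 1),
    n_events = length(tt), all_detached_episodes = 0, truncated = FALSE,
    t_final = 100), class = "ensemble_trace")
  s <- trace_summary(tr)
  expect_equal(s$velocity, 0.37, tolerance = 1e-10)
})

test_that("finite ensembles converge to the stationary solution under load", {
  # monotone force-velocity regime: the stationary operating point is unique
  cyc <- gentle_cycle()
  pot <- gentle_pot()
  fs <- solve_stationary(cyc, pot, 0.6)
  nm <- 50
  tr <- simulate_ensemble(cyc, pot, nm, F_load = nm * fs$F, t_end = 250,
                          seed = 11, thin = 2L)
  s <- trace_summary(tr)
  expect_lt(abs(s$efficiency - fs$eta), max(3 * s$se_efficiency, 0.01))
  expect_lt(abs(s$velocity - 0.6), max(3 * s$se_velocity, 0.05))
  # long-run ATP consumption matches N_m times the stationary cycle flux
  span <- diff(s$window)
  expect_equal(s$n_ATP / (span * nm), fs$r_ATPase, tolerance = 0.1)
  # no coordinated stepping: displacement increments concentrate near zero
  dX <- diff(tr$events$X)
  expect_lt(mean(abs(dX) > 0.5), 1e-3)
  expect_lt(abs(stats::median(dX)), 0.02)
})
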