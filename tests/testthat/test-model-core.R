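test_that("cycle construction enforces the structural conventions", {
  cyc <- motor_cycle(3, G = c(0, 0, -12, -22, -25), d = c(1, 1, 0.4, 0, 0),
                     alpha = c(1, 0.3, 0.7, 0, 0), k0 = c(2, 50, 30, 1),
                     dG_ATP = -25)
  expect_s3_class(cyc, "motor_cycle")
  expect_equal(cyc$n_states, 5L)
  expect_equal(cyc$k0[5], 1e5)  # hydrolysis default appended

  # attachment must carry alpha = 1, detachment alpha = 0
  expect_error(
    motor_cycle(2, G = c(0, 0, -20, -25), d = c(1, 1, 0, 0),
                alpha = c(0.5, 0.5, 0, 0), k0 = c(1, 1, 1), dG_ATP = -25),
    class = "motorlimits_validation_error")
  expect_error(
    motor_cycle(2, G = c(0, 0, -20, -25), d = c(1, 1, 0, 0),
                alpha = c(1, 0.5, 0.2, 0), k0 = c(1, 1, 1), dG_ATP = -25),
    class = "motorlimits_validation_error")
  # cyclic closure: last state's free energy must equal dG_ATP
  expect_error(
    motor_cycle(2, G = c(0, 0, -20, -24), d = c(1, 1, 0, 0),
                alpha = c(1, 0.5, 0, 0), k0 = c(1, 1, 1), dG_ATP = -25),
    class = "motorlimits_validation_error")
  # lever ordering
  expect_error(
    motor_cycle(3, G = c(0, 0, -12, -22, -25), d = c(1, 1, 1.2, 0, 0),
                alpha = c(1, 0.3, 0.7, 0, 0), k0 = c(2, 50, 30, 1),
                dG_ATP = -25),
    class = "motorlimits_validation_error")
  # error message names the violated invariant
  err <- tryCatch(
    motor_cycle(2, G = c(0, 0, -20, -25), d = c(1, 1, 0, 0),
                alpha = c(0.3, 0.5, 0, 0), k0 = c(1, 1, 1), dG_ATP = -25),
    error = function(e) e)
  expect_match(conditionMessage(err), "alpha\\[attachment\\]")
})

test_that("energy closure around the cycle returns dG_ATP exactly", {
  set.seed(1)
  for (i in 1:5) {
    cyc <- random_cycle()
    drops <- vapply(seq_len(cyc$n_states), function(t) motorlimits:::transition_dG(cyc, t),
                    numeric(1))
    expect_equal(sum(drops), cyc$dG_ATP, tolerance = 1e-12)
  }
})

test_that("potentials are convex, C1, anchored at zero, with exact forces", {
  pots <- list(
    elastic_potential("harmonic", kappa = 48),
    elastic_potential("two_regime", kappa = 48, x_a = -0.19),
    elastic_potential("piecewise", kappa = 48,
                      breakpoints = seq(-1.5, 1.5, length.out = 9),
                      curvatures = c(0, 0, 10, 30, 48, 48, 20, 5)))
  xs <- seq(-3, 3, length.out = 1201)
  h <- 1e-5
  for (pot in pots) {
    expect_equal(potential_energy(pot, 0), 0)
    expect_equal(potential_force(pot, 0), 0)
    cc <- potential_curvature(pot, xs)
    expect_true(all(cc >= -1e-12 & cc <= 48 + 1e-9))
    # force is the exact derivative of the energy
    fd <- (potential_energy(pot, xs + h) - potential_energy(pot, xs - h)) / (2 * h)
    expect_equal(potential_force(pot, xs), fd, tolerance = 1e-6)
    # energy continuous (convexity + C1 imply U >= 0 with minimum at 0)
    expect_true(all(potential_energy(pot, xs) >= -1e-12))
  }
})

test_that("two-regime potential: constant pushing force below x_a, harmonic limit", {
  pot <- elastic_potential("two_regime", kappa = 48, x_a = -0.19)
  xs <- seq(-3, -0.19, length.out = 50)
  expect_equal(potential_force(pot, xs), rep(48 * -0.19, 50))
  # continuity and differentiability at x_a
  expect_equal(potential_energy(pot, -0.19 - 1e-9),
               potential_energy(pot, -0.19 + 1e-9), tolerance = 1e-6)
  # converges to harmonic as x_a -> -Inf (sup norm on a fixed window)
  harm <- elastic_potential("harmonic", kappa = 48)
  xs <- seq(-6, 6, length.out = 601)
  dev <- vapply(c(-3, -4.5, -6), function(xa) {
    tr <- elastic_potential("two_regime", kappa = 48, x_a = xa)
    max(abs(potential_energy(tr, xs) - potential_energy(harm, xs)))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-9)
})

test_that("unnormalizable potentials are rejected", {
  expect_error(
    elastic_potential("piecewise", kappa = 48,
                      breakpoints = c(-1, 0, 1), curvatures = c(0, 48)),
    class = "motorlimits_validation_error")
  expect_error(elastic_potential("two_regime", kappa = 48, x_a = 0.3),
               class = "motorlimits_validation_error")
})

test_that("generalized detailed balance holds for every transition and strain", {
  set.seed(42)
  for (rep in 1:5) {
    cyc <- random_cycle()
    pot <- random_pot()
    xs <- runif(20, -1.5, 2)
    for (t in seq_len(cyc$n_bound + 1L)) {
      kf <- forward_rate(cyc, pot, t, xs)
      kr <- reverse_rate(cyc, pot, t, xs)
      dG <- motorlimits:::transition_dG(cyc, t)
      dU <- potential_energy(pot, xs - cyc$d[t + 1]) -
            potential_energy(pot, xs - cyc$d[t])
      expect_equal(kf / kr, exp(-(dG + dU)), tolerance = 1e-12)
    }
  }
})

test_that("alpha = 0 detachment is strain-independent; symmetric midpoint is neutral", {
  cyc <- nb2_cycle()
  pot <- nb2_pot()
  det <- motorlimits:::detach_transition(cyc)
  expect_equal(forward_rate(cyc, pot, det, c(-1, 0, 0.5, 2)), rep(1, 4))
  # halfway between the lever positions the elastic energies coincide
  mid <- (cyc$d[2] + cyc$d[3]) / 2
  expect_equal(forward_rate(cyc, pot, 2, mid), cyc$k0[2])
})

test_that("nondimensionalization reproduces the published stiffness and scales", {
  nd <- nondimensionalize(motor_units(3, 8, 4))
  expect_equal(nd$half_kappa, 24)
  # round trip through physical units
  K <- redimensionalize_stiffness(nd$kappa, 8, 4)
  expect_equal(K, 3)
  # velocity scale: dimensionless 1 at 100/s and 8 nm is 800 nm/s
  nd2 <- nondimensionalize(motor_units(3, 8, 4, k_ATP_rate = 100))
  expect_equal(nd2$velocity_scale, 800)
  expect_error(motor_units(-1, 8, 4), class = "motorlimits_validation_error")
})
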