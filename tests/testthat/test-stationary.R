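test_that("stationary fields satisfy the conservation laws on random models", {
  set.seed(7)
  for (rep in 1:6) {
    cyc <- random_cycle()
    pot <- random_pot()
    v <- runif(1, 0.05, 0.8)
    f <- solve_stationary(cyc, pot, v)
    expect_lt(f$residuals["normalization"], 1e-8)
    expect_lt(f$residuals["flux"], 1e-6)
    expect_lt(f$residuals["balance"], 1e-6)
    expect_true(all(f$sdot >= 0))              # pointwise non-negative
    expect_true(all(f$P >= 0))
    expect_lte(f$eta, 1)
    # total dissipation equals input power minus output power
    expect_equal(f$T_Sdot_total,
                 f$r_ATPase * (-cyc$dG_ATP) - v * f$F,
                 tolerance = 1e-6)
  }
})

test_that("thermodynamic equilibrium has zero flux and zero dissipation", {
  cyc <- motor_cycle(2, G = c(0, 0, -2, 0), d = c(1, 1, 0, 0),
                     alpha = c(1, 0.5, 0, 0), k0 = c(2, 5, 1), dG_ATP = 0,
                     k_hyd = 5)
  pot <- gentle_pot()
  f <- solve_stationary(cyc, pot, 0)
  expect_lt(max(abs(f$flux_by_transition)), 1e-10)
  expect_lt(f$T_Sdot_total, 1e-10)
  expect_equal(f$eta, 0)
  # v = 0 with dG != 0: a futile cycle, eta = 0 by definition
  f2 <- solve_stationary(gentle_cycle(), pot, 0)
  expect_equal(f2$eta, 0)
  expect_gt(f2$r_ATPase, 0)
})

test_that("negative velocities are rejected; grids must cover the stroke", {
  expect_error(solve_stationary(gentle_cycle(), gentle_pot(), -0.1),
               class = "motorlimits_validation_error")
  expect_error(solve_grid(0.5, 2, 0.01), class = "motorlimits_validation_error")
  expect_error(solve_grid(-1, 0.9, 0.01), class = "motorlimits_validation_error")
})

test_that("published two-state optimum is reproduced by a plain solve", {
  fx <- motor_fixture("nb2_optimal")
  f <- solve_stationary(fx$cycle, fx$potential, fx$v)
  # the efficiency at the published optimal parameters; the published peak
  # value is 42% (tolerance reflects optimizer/discretization differences)
  expect_equal(f$eta, 0.42, tolerance = 0.15)
  expect_gt(f$eta, 0.36)
  expect_gt(f$F, 0)
})

test_that("grid refinement leaves the efficiency unchanged below 1e-4", {
  cyc <- gentle_cycle()
  pot <- gentle_pot()
  g1 <- motorlimits:::auto_grid(cyc, pot, 0.4)
  g2 <- solve_grid(g1$x_min, g1$x_max, g1$dx, refine = 2L)
  e1 <- solve_stationary(cyc, pot, 0.4, g1)$eta
  e2 <- solve_stationary(cyc, pot, 0.4, g2)$eta
  expect_lt(abs(e1 - e2), 1e-4)
  # and on the stiff published fixture
  fx <- motor_fixture("nb2_optimal")
  ga <- motorlimits:::auto_grid(fx$cycle, fx$potential, fx$v)
  gb <- solve_grid(ga$x_min, ga$x_max, ga$dx, refine = 2L)
  ea <- solve_stationary(fx$cycle, fx$potential, fx$v, ga)$eta
  eb <- solve_stationary(fx$cycle, fx$potential, fx$v, gb)$eta
  expect_lt(abs(ea - eb), 1e-4)
})

test_that("efficiency does not depend on the duty ratio (hydrolysis rate)", {
  pot <- nb2_pot()
  e1 <- solve_stationary(nb2_cycle(k_hyd = 1e5), pot, 0.406)$eta
  e2 <- solve_stationary(nb2_cycle(k_hyd = 1e6), pot, 0.406)$eta
  expect_lt(abs(e1 - e2), 1e-6)
})

test_that("soft-spring solve matches the analytic closed forms", {
  cyc <- soft_cycle()
  pot <- soft_pot()
  # the detached dwell sets only the duty ratio; the efficiency and the
  # velocity predictions do not involve it
  m <- soft_limit_model(2, k_rates = c(400, 1), t_off = 0.5, kappa = 0.5, g = 25)
  vmax <- as.numeric(soft_velocity_max(m))
  pred <- soft_efficiency(m)
  f <- solve_stationary(cyc, pot, vmax / 2)
  expect_equal(f$eta, pred$eta, tolerance = 0.02)
  # linear force-velocity: F(vmax/2) is half of F(v -> 0)
  f0 <- solve_stationary(cyc, pot, 1e-3)
  expect_equal(f$F / f0$F, 0.5, tolerance = 0.02)
})

test_that("dissipation map integrates to the total and locates the main loss", {
  fx <- motor_fixture("nb2_optimal")
  f <- solve_stationary(fx$cycle, fx$potential, fx$v)
  dm <- dissipation_map(f)
  expect_true(all(dm$density >= 0))
  expect_equal(sum(dm$by_transition), dm$total, tolerance = 1e-12)
  expect_equal(dm$total, f$r_ATPase * 25 - f$v * f$F, tolerance = 1e-3)
  # at the two-state optimum the dominant loss is the premature detachment
  # of strained heads (the ATP-induced detachment transition)
  nb <- fx$cycle$n_bound
  expect_equal(unname(which.max(dm$by_transition[1:(nb + 1)])), nb + 1L)
})

test_that("force-velocity curve flags the anomalous region at the optimum", {
  fx <- motor_fixture("nb2_optimal")
  cv <- fv_curve(fx$cycle, fx$potential, seq(0.02, 0.9, length.out = 60))
  expect_true(all(cv$ok))
  expect_true(any(cv$anomalous))   # rising force below the efficiency peak
  h <- detect_hysteresis(cv)
  expect_true(h$multivalued)
  expect_true(all(h$fold_forces > 0))
})

test_that("hysteresis detection matches a brute-force scan on a synthetic fold", {
  # synthetic S-shaped curve with known fold forces
  v <- seq(0.01, 1, length.out = 200)
  Fv <- 2 - 2 * v + 1.5 * exp(-((v - 0.55) / 0.12)^2)
  curve <- structure(data.frame(v = v, F = Fv, eta = 0, r_ATPase = 1,
                                ok = TRUE, anomalous = FALSE),
                     class = c("fv_curve", "data.frame"))
  h <- detect_hysteresis(curve)
  expect_true(h$multivalued)
  # oracle: count crossings of F(v) = f over a dense force grid
  fgrid <- seq(min(Fv) + 1e-6, max(Fv) - 1e-6, length.out = 2000)
  nc <- vapply(fgrid, function(f) sum(abs(diff(sign(Fv - f))) > 0), numeric(1))
  oracle <- range(fgrid[nc >= 2])
  expect_equal(h$interval[1], oracle[1], tolerance = 0.02)
  expect_equal(h$interval[2], oracle[2], tolerance = 0.02)

  # monotone curve: empty interval
  mono <- structure(data.frame(v = v, F = 2 - 2 * v, eta = 0, r_ATPase = 1,
                               ok = TRUE, anomalous = FALSE),
                    class = c("fv_curve", "data.frame"))
  expect_false(detect_hysteresis(mono)$multivalued)
  # non-monotone but too sparse: refuses rather than guessing
  sparse <- curve[seq(1, 200, by = 10), ]
  class(sparse) <- c("fv_curve", "data.frame")
  expect_error(detect_hysteresis(sparse), class = "motorlimits_grid_error")
})

test_that("efficiency peak search finds the soft-limit optimum at vmax/2", {
  cyc <- soft_cycle()
  pot <- soft_pot()
  vmax <- 2 * (1 - 1 / 2) / (1 / 400 + 1)
  pk <- efficiency_peak(cyc, pot, c(0.05, 0.95), tol = 1e-3)
  expect_equal(pk$v_star, vmax / 2, tolerance = 0.02)
  expect_false(pk$boundary)
  expect_equal(pk$eta_star, 0.005, tolerance = 0.02)
})
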