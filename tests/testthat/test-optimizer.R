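test_that("scenario construction validates caps and target velocities", {
  expect_s3_class(motor_scenario("free_velocity", 2), "motor_scenario")
  expect_error(motor_scenario("free_velocity", 2, half_kappa_cap = -1),
               class = "motorlimits_validation_error")
  expect_error(motor_scenario("fixed_velocity", 3),
               class = "motorlimits_validation_error")
  expect_error(motor_scenario("free_velocity", 2, v_target = 0.5),
               class = "motorlimits_validation_error")
})

test_that("parameter mapping honours the scenario conventions", {
  scn <- motor_scenario("free_velocity", 3, half_kappa_cap = 40)
  spec <- motorlimits:::par_spec(scn)
  th <- (spec$lower + pmin(spec$upper, 10)) / 2
  names(th) <- spec$name
  th[c("log_v", "G2", "G3", "alpha1", "alpha2")] <- c(log(0.2), -12, -22, 0.3, 0.6)
  th[c("log_k0", "log_k1", "log_k2", "s2", "log_half_kappa")] <-
    c(log(2), log(50), log(30), 0.4, log(25))
  m <- motorlimits:::build_model(scn, th, spec)
  expect_equal(m$v, 0.2)
  expect_equal(m$cycle$G, c(0, 0, -12, -22, -25))
  expect_equal(m$cycle$alpha, c(1, 0.3, 0.6, 0, 0))
  expect_equal(m$cycle$d, c(1, 1, 0.4, 0, 0))       # s2 scales the stroke
  expect_equal(m$cycle$k0[4], 1)                    # detachment = rate unit
  expect_equal(m$pot$kappa, 50)

  # fixed-velocity scenario: ADP cap acts through detailed balance
  scn2 <- motor_scenario("fixed_velocity", 3, v_target = 0.1,
                         half_kappa_cap = 24, adp_ratio_cap = 0.01)
  spec2 <- motorlimits:::par_spec(scn2)
  expect_false("log_v" %in% spec2$name)
  expect_lte(max(spec2$upper[spec2$name == "log_kADP"]), log(0.01) + 1e-12)
  th2 <- setNames((spec2$lower + pmin(spec2$upper, 10)) / 2, spec2$name)
  th2[c("G2", "G3")] <- c(-15.1, -22.3)
  th2["log_kADP"] <- log(0.01)
  th2["log_kdet"] <- log(1)
  m2 <- motorlimits:::build_model(scn2, th2, spec2)
  # reverse rate of the ADP-release transition equals the capped binding rate
  kADP <- m2$cycle$k0[3] * exp(m2$cycle$G[4] - m2$cycle$G[3])
  expect_equal(kADP, 0.01, tolerance = 1e-12)
  expect_equal(m2$cycle$k0[4], 1)
  expect_equal(m2$v, 0.1)
})

test_that("the ADP dissociation constant follows the release free energy", {
  scn <- motor_scenario("fixed_velocity", 3, v_target = 0.1,
                        half_kappa_cap = 24, adp_ratio_cap = 0.01)
  spec <- motorlimits:::par_spec(scn)
  th <- setNames((spec$lower + pmin(spec$upper, 10)) / 2, spec$name)
  th[c("G2", "G3")] <- c(-15.1, -22.3)
  th[c("log_k0", "log_k1")] <- c(log(2.33), log(100))
  th["log_kADP"] <- log(0.01); th["log_kdet"] <- 0
  th["s2"] <- 0.25; th["log_half_kappa"] <- log(24)
  o <- motorlimits:::make_optimum(scn, th, diagnostics = NULL, spec)
  # K_D/[ADP] = exp(G_ADPstate - G_rigor): uphill release means K_D < [ADP]
  expect_equal(o$K_D_ADP, exp(-15.1 + 22.3))
  # the reported optimum reproduces its efficiency when re-solved
  f <- solve_stationary(o$cycle, o$potential, o$v_star)
  expect_equal(o$eta_max, f$eta, tolerance = 1e-9)
})

test_that("multi-start optimization is reproducible and self-consistent", {
  scn <- motor_scenario("free_velocity", 2, dG_ATP = -25, half_kappa_cap = 10)
  o1 <- maximize_free_velocity(scn, starts = 3, seed = 21)
  o2 <- maximize_free_velocity(scn, starts = 3, seed = 21)
  expect_identical(o1$theta, o2$theta)
  expect_identical(o1$eta_max, o2$eta_max)
  expect_gt(o1$eta_max, 0)
  expect_lt(o1$eta_max, 1)
  # re-evaluation consistency of the reported optimum
  f <- solve_stationary(o1$cycle, o1$potential, o1$v_star)
  expect_equal(o1$eta_max, f$eta, tolerance = 1e-9)
  # stored-elastic-energy bound: with kappa/2 <= g, eta <= (kappa/2)/g
  hk <- exp(o1$theta[["log_half_kappa"]])
  expect_lte(o1$eta_max, hk / 25 + 1e-6)
})

test_that("two-regime refit recovers a known transition point", {
  pot <- elastic_potential("two_regime", kappa = 48, x_a = -0.19)
  fit <- motorlimits:::fit_two_regime(pot, kappa_cap = 48)
  expect_equal(fit$x_a, -0.19, tolerance = 1e-3)
  expect_equal(fit$kappa, 48, tolerance = 1e-3)
  harm <- elastic_potential("harmonic", kappa = 48)
  fit2 <- motorlimits:::fit_two_regime(harm, kappa_cap = 48)
  expect_lt(fit2$x_a, -1)   # compliant region pushed out of the window
})
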