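test_that("soft-limit closed forms reproduce the printed formulas", {
  # N_B = 2, t_on = 1: v_max = d/t_on
  m2 <- soft_limit_model(2, c(1e6, 1 / (1 - 1e-6)), kappa = 0.5, g = 25)
  expect_equal(as.numeric(soft_velocity_max(m2)), 1, tolerance = 1e-5)
  # N_B = 4, t_on = 0.5: v_max = 2*(3/4)/0.5 = 3
  m4 <- soft_limit_model(4, rep(8, 4), kappa = 0.5, g = 25)
  expect_equal(m4$t_on, 0.5)
  expect_equal(as.numeric(soft_velocity_max(m4)), 3)
  # large N_B: v_max -> 2 d / t_on
  m40 <- soft_limit_model(40, rep(40, 40), kappa = 0.5, g = 25)
  expect_equal(as.numeric(soft_velocity_max(m40)), 2 * (1 - 1 / 40))

  # efficiency: N_B = 2, kappa/2 = 1, g = 25 -> 0.02
  me <- soft_limit_model(2, c(100, 1), kappa = 2, g = 25)
  expect_equal(soft_efficiency(me)$eta, 0.02)
  expect_equal(soft_efficiency(me)$work_per_ATP, 0.5)
  # linear growth in kappa at fixed N_B
  e1 <- soft_efficiency(soft_limit_model(3, c(100, 2, 2), kappa = 0.4, g = 25))$eta
  e2 <- soft_efficiency(soft_limit_model(3, c(100, 2, 2), kappa = 0.8, g = 25))$eta
  expect_equal(e2 / e1, 2)
  # always below the stored-energy ceiling kappa/(2g); equality only as NB grows
  for (nb in c(2, 5, 20)) {
    m <- soft_limit_model(nb, rep(nb, nb), kappa = 0.5, g = 25)
    expect_lt(soft_efficiency(m)$eta, 0.5 / 50)
  }
  # warns outside the stated validity regime
  expect_warning(soft_limit_model(2, c(10, 1), kappa = 10, g = 25), "dubious")
})

test_that("soft-limit operating point sits at half stall force, half max velocity", {
  m <- soft_limit_model(2, c(400, 1), t_off = 1.005, kappa = 1, g = 25)
  op <- soft_operating_point(m)
  expect_equal(op$v_opt_frac, 0.5)
  expect_equal(op$F_opt_frac, 0.5)
  # F_stall = kappa * t_on / t_cycle: with t_on ~ 1 and t_cycle ~ 2 -> 0.5
  expect_equal(op$F_stall, 1 * m$t_on / m$t_cycle)
  expect_equal(op$F_stall, 0.5, tolerance = 0.01)
  # doubling t_cycle at fixed t_on halves the stall force
  m2 <- soft_limit_model(2, c(400, 1), t_off = 1.005 + m$t_cycle, kappa = 1, g = 25)
  expect_equal(soft_operating_point(m2)$F_stall, op$F_stall / 2, tolerance = 0.01)
})

test_that("soft-limit force-velocity line has the right endpoints and peak", {
  m <- soft_limit_model(3, c(200, 2, 2), t_off = 0.3, kappa = 0.5, g = 25)
  vmax <- as.numeric(soft_velocity_max(m))
  cv <- soft_fv_curve(m, c(0, vmax / 2, vmax))
  expect_equal(cv$eta[1], 0)                     # v = 0
  expect_equal(cv$F[3], 0, tolerance = 1e-12)    # F(vmax) = 0
  expect_equal(cv$eta[3], 0, tolerance = 1e-12)
  # peak of eta at vmax/2
  vs <- seq(0, vmax, length.out = 401)
  etas <- soft_fv_curve(m, vs)$eta
  expect_equal(vs[which.max(etas)], vmax / 2, tolerance = 0.01)
  expect_equal(max(etas), soft_efficiency(m)$eta, tolerance = 1e-10)
})

test_that("detachment-time density is hypoexponential with narrowing CV", {
  # single stage after the fast first transition: pure exponential, CV = 1
  m2 <- soft_limit_model(2, c(1e4, 2), kappa = 0.5, g = 25)
  d2 <- detachment_time_density(m2)
  expect_equal(d2$cv, 1)
  ts <- seq(0, 8, by = 1e-3)
  expect_equal(d2$pdf(0.5), stats::dexp(0.5, 2))
  # four equal stages: Erlang, CV = 1/2, density matches dgamma
  m5 <- soft_limit_model(5, c(1e4, rep(4, 4)), kappa = 0.5, g = 25)
  d5 <- detachment_time_density(m5)
  expect_equal(d5$cv, 0.5)
  expect_equal(d5$pdf(c(0.3, 1, 2.5)),
               stats::dgamma(c(0.3, 1, 2.5), shape = 4, rate = 4),
               tolerance = 1e-8)
  # integrates to one with the correct mean
  ig <- sum(d5$pdf(ts)) * 1e-3
  expect_equal(ig, 1, tolerance = 1e-4)
  expect_equal(d5$mean, 1)
  expect_equal(sum(ts * d5$pdf(ts)) * 1e-3, d5$mean, tolerance = 1e-3)
  # distinct rates: density still integrates to one
  md <- soft_limit_model(4, c(1e4, 1, 2.5, 7), kappa = 0.5, g = 25)
  dd <- detachment_time_density(md)
  expect_equal(sum(dd$pdf(ts)) * 1e-3, 1, tolerance = 1e-3)
  # CV strictly decreases with the number of equal stages at fixed t_on
  cvs <- vapply(2:6, function(nb) {
    m <- soft_limit_model(nb, c(1e4, rep(nb - 1, nb - 1)), kappa = 0.5, g = 25)
    detachment_time_density(m)$cv
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
})
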