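test_that("velocity profile has the closed-form shape, no slip and correct flux", {
  R <- 0.2e-3
  Q <- pi * R^2 * 9e-3
  # Newtonian limit: parabolic with centerline twice the mean velocity
  newt <- velocity_profile(power_law_fluid(2, 1), R, Q, n_radial = 201)
  expect_equal(max(newt$u), 2 * 9e-3, tolerance = 1e-12)
  expect_equal(newt$u[nrow(newt)], 0)
  # strongly shear-thinning: centerline/mean = (3n+1)/(n+1)
  thin <- velocity_profile(power_law_fluid(5.78, 0.12), R, Q)
  expect_equal(max(thin$u) / 9e-3, (3 * 0.12 + 1) / (0.12 + 1),
               tolerance = 1e-12)
  expect_equal(max(thin$u) / 9e-3, 1.2143, tolerance = 1e-4)
  # the profile integrates back to the imposed flow rate
  for (g in fx$gels) {
    prof <- velocity_profile(g, R, Q, n_radial = 2001)
    flux <- sum(2 * pi * prof$r * prof$u) * diff(prof$r[1:2])
    expect_equal(flux, Q, tolerance = 1e-5)
  }
})

test_that("plug fraction depends only on n and matches the closed form", {
  expect_equal(plug_fraction(power_law_fluid(5.78, 0.12)), 0.05^(0.12 / 1.12))
  expect_equal(plug_fraction(power_law_fluid(5.78, 0.12)), 0.7254,
               tolerance = 1e-4)
  expect_equal(plug_fraction(power_law_fluid(41.98, 0.02)), 0.9429,
               tolerance = 1e-4)
  expect_equal(plug_fraction(power_law_fluid(1, 1)), sqrt(0.05))
  expect_error(plug_fraction(power_law_fluid(1, 1), threshold = 1), "between")
  # strictly decreasing in n
  ns <- seq(0.02, 1, length.out = 25)
  pf <- vapply(ns, function(n) plug_fraction(power_law_fluid(1, n)), numeric(1))
  expect_true(all(diff(pf) < 0))
})

test_that("Rabinowitsch-Mooney wall shear matches hand-derived values", {
  R <- 0.2e-3
  Q <- pi * R^2 * 9e-3
  ws <- wall_shear(power_law_fluid(5.78, 0.12), R, Q)
  expect_equal(ws$wall_shear_rate, (3 * 0.12 + 1) / (4 * 0.12) * 180,
               tolerance = 1e-12)
  expect_equal(ws$wall_shear_rate, 510, tolerance = 1e-3)
  expect_equal(ws$wall_shear_stress, 12.2, tolerance = 1e-2)
  ws2 <- wall_shear(power_law_fluid(41.98, 0.02), R, Q)
  expect_equal(ws2$wall_shear_stress, 49.0, tolerance = 1e-2)
  # Newtonian limit: wall shear rate is exactly 8V/D
  wsn <- wall_shear(power_law_fluid(3, 1), R, Q)
  expect_equal(wsn$wall_shear_rate, 180, tolerance = 1e-12)
  # stress increases with K at fixed kinematics
  taus <- vapply(c(1, 5, 20, 40), function(K) {
    wall_shear(power_law_fluid(K, 0.05), R, Q)$wall_shear_stress
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("cylinder pressure drop is 2 tau_w L / R and cones degenerate to it", {
  f <- power_law_fluid(5.78, 0.12)
  R <- 0.2e-3
  Q <- pi * R^2 * 9e-3
  needle <- extrusion_segment("cylinder", 20e-3, R)
  dp <- segment_pressure_drop(f, needle, Q)
  tau_w <- wall_shear(f, R, Q)$wall_shear_stress
  expect_equal(dp, 2 * tau_w * 20e-3 / R, tolerance = 1e-12)
  expect_equal(dp, 2442, tolerance = 1e-3)
  degenerate <- extrusion_segment("cone", 20e-3, R, R)
  expect_equal(segment_pressure_drop(f, degenerate, Q), dp, tolerance = 1e-12)
})

test_that("cone integration converges as the slice count grows", {
  f <- power_law_fluid(41.98, 0.02)
  cone <- extrusion_segment("cone", 10e-3, 6e-3, 0.2e-3)
  Q <- ref_flow_rate()
  dp400 <- segment_pressure_drop(f, cone, Q, n_slices = 400)
  dp800 <- segment_pressure_drop(f, cone, Q, n_slices = 800)
  expect_lt(abs(dp800 - dp400) / dp400, 1e-4)
})

test_that("the three rheological models rank as expected in the needle", {
  R <- 0.2e-3
  Q <- pi * R^2 * 9e-3
  needle <- extrusion_segment("cylinder", 16e-3, R)
  gref <- average_shear_rate(2 * R, 9e-3)
  for (g in fx$gels) {
    dp3 <- segment_pressure_drop(g, needle, Q, model = "power_law")
    dp1 <- segment_pressure_drop(g, needle, Q, model = "newtonian_K")
    dp2 <- segment_pressure_drop(g, needle, Q, model = "newtonian_avg_shear",
                                 reference_shear_rate = gref)
    expect_gt(dp1 / dp3, 50)     # crude Newtonian model overshoots hugely
    expect_lt(dp2, dp3)          # avg-shear model underestimates for n < 1
    err <- modeling_error(dp2, dp3)
    expect_equal(err, 100 * ((4 * g$n / (3 * g$n + 1))^g$n - 1),
                 tolerance = 1e-9)
  }
  # the two closed-form anchor values
  g12 <- fx$gels$C20_pH3.7
  dp3 <- segment_pressure_drop(g12, needle, Q)
  dp1 <- segment_pressure_drop(g12, needle, Q, model = "newtonian_K")
  dp2 <- segment_pressure_drop(g12, needle, Q, model = "newtonian_avg_shear",
                               reference_shear_rate = gref)
  expect_equal(dp1 / dp3, 85, tolerance = 0.01)
  expect_equal(modeling_error(dp2, dp3), -11.75, tolerance = 1e-3)
  g02 <- fx$gels$C30_pH4.9
  dp3b <- segment_pressure_drop(g02, needle, Q)
  dp2b <- segment_pressure_drop(g02, needle, Q, model = "newtonian_avg_shear",
                                reference_shear_rate = gref)
  expect_equal(modeling_error(dp2b, dp3b), -5.04, tolerance = 1e-2)
  expect_equal(modeling_error(7, 7), 0)
  expect_error(modeling_error(1, 0), "positive")
})

test_that("model 2 equals the power law exactly when n = 1", {
  newt <- power_law_fluid(3, 1)
  needle <- extrusion_segment("cylinder", 16e-3, 0.2e-3)
  Q <- pi * (0.2e-3)^2 * 9e-3
  dp2 <- segment_pressure_drop(newt, needle, Q, model = "newtonian_avg_shear",
                               reference_shear_rate = 123)
  dp3 <- segment_pressure_drop(newt, needle, Q, model = "power_law")
  expect_equal(dp2, dp3, tolerance = 1e-12)
})

test_that("system flow chains segments with zero outlet pressure", {
  sys <- fx$system
  sf <- system_flow(sys, fx$gels$C30_pH4.9, 1e-5)
  expect_equal(sf$outlet_velocity, 9e-3, tolerance = 1e-12)
  expect_equal(max(sf$segments$wall_shear_stress), 49.0, tolerance = 1e-2)
  # pressure is zero at the tip, maximal at the piston face, monotone
  expect_equal(sf$profile$pressure[nrow(sf$profile)], 0)
  expect_equal(sf$profile$pressure[1], sf$total_pressure)
  expect_true(all(diff(sf$profile$pressure) < 0))
  # total drop is in the kPa range for the stiffest gel
  expect_gt(sf$total_pressure, 1e3)
  expect_lt(sf$total_pressure, 1e5)
  # total drop decreases as the needle radius increases
  totals <- vapply(fx$needle_radii, function(R) {
    system_flow(default_extrusion_system(needle_radius = R),
                fx$gels$C20_pH3.7, 1e-5)$total_pressure
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_profile(sf, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(sf$profile))
})

test_that("radial quadrature oracle inverts the closed-form pressure drop", {
  # Newtonian limit recovers Hagen-Poiseuille exactly
  mu <- 0.7
  R <- 0.2e-3
  G <- 5e6
  Q_hp <- pi * R^4 * G / (8 * mu)
  expect_equal(radial_quadrature_oracle(power_law_fluid(mu, 1), R, G), Q_hp,
               tolerance = 1e-8)
  expect_equal(radial_quadrature_oracle(power_law_fluid(mu, 1), R, 0), 0)
  # round trip on the worked needle example
  f <- power_law_fluid(5.78, 0.12)
  Q <- pi * R^2 * 9e-3
  dp <- segment_pressure_drop(f, extrusion_segment("cylinder", 20e-3, R), Q)
  expect_equal(radial_quadrature_oracle(f, R, dp / 20e-3), Q,
               tolerance = 1e-3)
  # all reference gels at all needle radii, < 0.1% relative error
  for (g in fx$gels) {
    for (R_i in fx$needle_radii) {
      Q_i <- ref_flow_rate()
      seg <- extrusion_segment("cylinder", 16e-3, R_i)
      grad <- segment_pressure_drop(g, seg, Q_i) / 16e-3
      expect_equal(radial_quadrature_oracle(g, R_i, grad), Q_i,
                   tolerance = 1e-3)
    }
  }
})
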