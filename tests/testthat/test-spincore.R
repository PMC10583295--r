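test_that("dipolar frequency vanishes for zero coupling and under the rotor average", {
  ph <- 2 * pi * (0:719) / 720
  expect_equal(dipolar_frequency(0.7, 1.1, ph, 0), rep(0, 720))
  for (bg in list(c(0.3, 0), c(1.2, 2.0), c(pi / 2, 4))) {
    expect_lt(abs(mean(dipolar_frequency(bg[1], bg[2], ph, 22000))), 1e-10)
  }
})

test_that("static limit recovers the full coupling (analytic tensor formula)", {
  # no rotor tilt, tensor along the field: P2 = 1
  expect_equal(dipolar_frequency(0, 0, 0.3, 22000, rotor_tilt = 0), 22000)
  # direct evaluation of b * P2(cos(theta)) at a generic static geometry
  b <- 0.9; g <- 1.3; tilt <- 0.5; ph <- 0.7
  ct <- cos(tilt) * cos(b) - sin(tilt) * sin(b) * cos(ph + g)
  expect_equal(dipolar_frequency(b, g, ph, 22000, rotor_tilt = tilt),
               22000 * 0.5 * (3 * ct^2 - 1), tolerance = 1e-12)
})

test_that("zero coupling leaves the observable at 1 at R-block boundaries", {
  cond <- unit_cond(0)
  sch <- r1817_schedule(5000, n_blocks = 3)
  tr <- propagate(sch, cond, c(0.9, 0.4), sample_times = (0:3) * 2e-4)
  expect_equal(tr$observable, rep(1, 4), tolerance = 1e-9)
  m <- simulate_modulation(cond, 8)
  expect_equal(m$amplitude, rep(1, 8), tolerance = 1e-9)
})

test_that("density-matrix propagation is unitary and trace-preserving", {
  cond <- unit_cond(0.1)
  sch <- r1817_schedule(5000, rf_scale = 1.1, offset_hz = 800, n_blocks = 4)
  tr <- propagate(sch, cond, c(0.8, 1.0), sample_times = (0:4) * 2e-4)
  expect_lt(attr(tr, "unitarity_error"), 1e-9)
  expect_lt(attr(tr, "trace_error"), 1e-9)
  expect_true(all(abs(tr$observable) <= 1 + 1e-9))
  expect_equal(tr$observable[1], 1, tolerance = 1e-9)
})

test_that("dense propagator matches the compiled modulation core", {
  cond <- unit_cond(0.1)
  sch <- r1817_schedule(5000, n_blocks = 5)
  tr <- propagate(sch, cond, c(0.9, 0.3), sample_times = (0:5) * 2e-4)
  cc <- rpdlf:::rpdlf_single_orientation_cpp(0.9, 0.3, 2200, 5000, 1, 0,
                                             6L, 32L, FALSE)
  expect_equal(tr$observable, as.numeric(cc), tolerance = 1e-9)
})

test_that("single-orientation trajectory is a power of one fixed-axis rotation", {
  # a + (1 - a) cos(2 pi f t): one orientation-dependent effective
  # frequency plus the second-order constant pedestal
  t1 <- (0:63) * 2e-4
  for (beta in c(pi / 4, 1.1)) {
    s <- rpdlf:::rpdlf_single_orientation_cpp(beta, 0.3, 2200, 5000, 1, 0,
                                              64L, 32L, TRUE)
    ft <- fit_rotation_power(t1, as.numeric(s))
    expect_lt(ft$rms, 1e-3)
    expect_gt(ft$freq, 0)
  }
})

test_that("halving the internal time step barely changes the modulation", {
  cond <- unit_cond(0.1)
  m1 <- simulate_modulation(cond, 64, n_sub = 32)
  m2 <- simulate_modulation(cond, 64, n_sub = 64)
  expect_lt(max(abs(m1$amplitude - m2$amplitude)), 1e-4)
})

test_that("too coarse a sub-step raises a configuration error", {
  cond <- unit_cond(0.1)
  sch <- r1817_schedule(5000, n_blocks = 1)
  expect_error(propagate(sch, cond, c(0.9, 0.3), sample_times = c(0, 2e-4),
                         n_sub = 2L),
               class = "rpdlf_config_error")
})

test_that("powder-averaged modulation is invariant under a gamma-origin shift", {
  p <- powder_orientations("zcw", 233)
  shifted <- p
  shifted$gamma <- (p$gamma + 0.7) %% (2 * pi)
  cond1 <- simulation_conditions(s_ch = 0.08, powder = p)
  cond2 <- simulation_conditions(s_ch = 0.08, powder = shifted)
  m1 <- simulate_modulation(cond1, 32)
  m2 <- simulate_modulation(cond2, 32)
  expect_lt(max(abs(m1$amplitude - m2$amplitude)), 1e-3)
})
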