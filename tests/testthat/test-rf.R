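test_that("Gaussian RF distribution: degeneracy, symmetry, normalization", {
  d0 <- gaussian_rf_distribution(sigma = 0)
  expect_identical(d0$kind, "delta")
  expect_equal(d0$nodes, 1)
  expect_equal(d0$weights, 1)
  d1 <- gaussian_rf_distribution(n_nodes = 1)
  expect_identical(d1$kind, "delta")

  d <- gaussian_rf_distribution(center = 1, sigma = 0.1, n_nodes = 21)
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_equal(d$weights, rev(d$weights), tolerance = 1e-12)
  expect_equal(sum(d$weights * d$nodes), 1, tolerance = 1e-6)
  expect_error(gaussian_rf_distribution(sigma = -0.1),
               class = "rpdlf_value_error")
})

test_that("delta distribution integrates to the single-scale modulation exactly", {
  cond <- unit_cond(0.08)
  m1 <- integrate_over_rf(cond, delta_rf_distribution(), 16)
  m2 <- simulate_modulation(cond, 16)
  expect_equal(m1$amplitude, m2$amplitude, tolerance = 1e-12)
})

test_that("RF integration is linear in the weights", {
  cond <- unit_cond(0.08)
  two <- rf_distribution(c(0.9, 1.1), c(0.5, 0.5))
  m <- integrate_over_rf(cond, two, 16)
  ma <- integrate_over_rf(cond, delta_rf_distribution(0.9), 16)
  mb <- integrate_over_rf(cond, delta_rf_distribution(1.1), 16)
  expect_equal(m$amplitude, (ma$amplitude + mb$amplitude) / 2,
               tolerance = 1e-12)
  expect_equal(m$amplitude[1], 1, tolerance = 1e-12)
})

test_that("inhomogeneity raises the long-time average, monotonically in sigma", {
  cond <- unit_cond(0.035)
  lt_mean <- vapply(c(0, 0.05, 0.1, 0.15), function(sg) {
    d <- if (sg == 0) delta_rf_distribution()
         else gaussian_rf_distribution(sigma = sg, n_nodes = 11)
    m <- integrate_over_rf(cond, d, 64)
    mean(m$amplitude[33:64])
  }, numeric(1))
  expect_true(all(diff(lt_mean) > 0))
})

test_that("Gaussian-weighted modulation shows a central (middle) spectral peak", {
  cond <- unit_cond(0.035)
  ideal <- simulate_modulation(cond, 64)
  inhom <- integrate_over_rf(cond, unit_rf(), 64)
  expect_gt(mean(inhom$amplitude[33:64]), mean(ideal$amplitude[33:64]))
  # remove each curve's mean-free oscillation: compare zero-frequency power
  sp_id <- dipolar_spectrum(ideal)
  sp_in <- dipolar_spectrum(inhom)
  centre <- which.min(abs(sp_in$freq))
  expect_gt(sp_in$intensity[centre], sp_id$intensity[centre])
  # and the central intensity dominates the inhomogeneous spectrum
  expect_equal(which.max(sp_in$intensity), centre)
})

test_that("nutation analysis recovers a single frequency as a delta", {
  t <- (0:511) * 5e-6
  est <- estimate_rf_distribution(t, cos(2 * pi * 45000 * t),
                                  nominal_hz = 45000)
  expect_identical(est$kind, "delta")
  expect_equal(est$params$center_hz, 45000, tolerance = 0.01 * 45000)
})

test_that("nutation analysis recovers the generating Gaussian width", {
  # oracle: the distribution that generated the synthetic nutation decay
  t <- (0:511) * 5e-6
  nu <- seq(45000 * (1 - 4 * 0.08), 45000 * (1 + 4 * 0.08), length.out = 201)
  w <- dnorm(nu, 45000, 0.08 * 45000); w <- w / sum(w)
  sig <- vapply(t, function(tt) sum(w * cos(2 * pi * nu * tt)), numeric(1))
  est <- estimate_rf_distribution(t, sig, nominal_hz = 45000)
  expect_identical(est$kind, "gaussian")
  expect_equal(est$params$sigma, 0.08, tolerance = 0.15 * 0.08)
  expect_equal(est$params$center, 1, tolerance = 0.02)

  # 5% additive noise moves the recovered center by less than 1%
  set.seed(11)
  noisy <- sig + rnorm(length(sig), 0, 0.05)
  est_n <- estimate_rf_distribution(t, noisy, nominal_hz = 45000)
  expect_lt(abs(est_n$params$center - est$params$center), 0.01)
})

test_that("a flat spectrum raises an estimation error", {
  set.seed(4)
  t <- (0:255) * 5e-6
  expect_error(estimate_rf_distribution(t, rnorm(256)),
               class = "rpdlf_estimation_error")
})

test_that("RF table round-trips through two-column text", {
  d <- gaussian_rf_distribution(sigma = 0.07, n_nodes = 9)
  p <- tempfile(fileext = ".txt")
  save_rf_distribution(d, p)
  d2 <- load_rf_distribution(p)
  expect_equal(d2$nodes, d$nodes, tolerance = 1e-12)
  expect_equal(d2$weights, d$weights, tolerance = 1e-12)
  expect_identical(d2$kind, "gaussian")
})
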