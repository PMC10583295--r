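test_that("line broadening follows the stated exponential convention", {
  m <- dipolar_modulation(c(0, 0.005, 0.01), c(1, 0.9, 0.8))
  expect_equal(apply_line_broadening(m, 0)$amplitude, m$amplitude)
  lb14 <- apply_line_broadening(m, 14)
  expect_equal(lb14$amplitude[3] / m$amplitude[3], exp(-pi * 14 * 0.01),
               tolerance = 1e-12)
  expect_equal(lb14$amplitude[1], 1)
  # monotone in lb for t1 > 0
  lb30 <- apply_line_broadening(m, 30)
  expect_true(all(abs(lb30$amplitude[-1]) < abs(lb14$amplitude[-1])))
  expect_error(apply_line_broadening(m, -1), class = "rpdlf_value_error")
})

test_that("chi-square basics: zero at equality, n*c^2 for a constant shift, permutation invariant", {
  a <- c(1, 0.8, 0.3, -0.1)
  expect_equal(chi_square(a, a), 0)
  expect_equal(chi_square(a + 0.2, a), 4 * 0.04, tolerance = 1e-12)
  p <- c(3, 1, 4, 2)
  expect_equal(chi_square(a[p], (a + 0.1)[p]), chi_square(a, a + 0.1))
  m1 <- dipolar_modulation(c(0, 1e-3), c(1, 0.5))
  m2 <- dipolar_modulation(c(0, 2e-3), c(1, 0.5))
  expect_error(chi_square(m1, m2), class = "rpdlf_value_error")
})

test_that("noiseless self-consistency: database curve is recovered exactly", {
  db <- unit_ideal_db()
  dat <- as_data(db, interpolate_modulation(db, 0.1))
  fit <- fit_components(dat, db, 1)
  expect_equal(fit$components$s, 0.1, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-12)
  expect_lt(fit$line_broadening, 0.1)
})

test_that("matched-model single-component recovery under noise", {
  # median absolute error < 0.005 over replicates for s in a lipid-like range
  db <- unit_inhom_db()
  set.seed(101)
  for (s in c(0.02, 0.05, 0.1)) {
    base <- integrate_over_rf(unit_cond(s), unit_rf(), 32)$amplitude
    err <- replicate(10, {
      y <- base
      y[-1] <- y[-1] + rnorm(31, 0, 0.02)
      fit <- fit_components(as_data(db, y), db, 1)
      abs(fit$components$s - s)
    })
    expect_lt(median(err), 0.005)
  }
})

test_that("ideal-model fits of inhomogeneity data inflate the damping estimate", {
  dbI <- unit_ideal_db()
  dbG <- unit_inhom_db()
  base <- integrate_over_rf(unit_cond(0.023), unit_rf(), 32)$amplitude
  set.seed(202)
  worse <- replicate(20, {
    y <- base
    y[-1] <- y[-1] + rnorm(31, 0, 0.02)
    dat <- as_data(dbG, y)
    f_match <- fit_components(dat, dbG, 1)
    f_ideal <- fit_components(dat, dbI, 1)
    f_ideal$line_broadening > f_match$line_broadening
  })
  expect_gte(mean(worse), 0.8)
})

test_that("two close components are identified from noiseless 32-point data", {
  db <- unit_inhom_db()
  base <- 0.5 * integrate_over_rf(unit_cond(0.085), unit_rf(), 32)$amplitude +
          0.5 * integrate_over_rf(unit_cond(0.096), unit_rf(), 32)$amplitude
  fit <- fit_components(as_data(db, base), db, 2)
  expect_equal(fit$components$s[1], 0.085, tolerance = 0.003)
  expect_equal(fit$components$s[2], 0.096, tolerance = 0.003)
})

test_that("short acquisitions forgive the ideal model; long ones do not", {
  dbI <- unit_ideal_db()
  dbG <- unit_inhom_db()
  s_true <- 0.028
  base <- integrate_over_rf(unit_cond(s_true), unit_rf(), 32)$amplitude
  # damping-free fits isolate the bias of the RF model itself
  est <- function(db, k) fit_components(as_data(db, base, k), db, 1,
                                        lb = "fixed")$components$s
  # 8 points: both models agree closely
  expect_lt(abs(est(dbI, 8) - est(dbG, 8)), 0.005)
  # 32 points: the ideal model's error exceeds the matched model's
  expect_gt(abs(est(dbI, 32) - s_true), abs(est(dbG, 32) - s_true))
})

test_that("insufficient data and grid mismatches are rejected", {
  db <- unit_ideal_db()
  expect_error(fit_components(dipolar_modulation(db$t1[1:2],
                                                 db$curves[1, 1:2]), db, 1),
               class = "rpdlf_data_error")
  off <- dipolar_modulation(db$t1[1:8] + c(0, rep(1e-5, 7)),
                            db$curves[1, 1:8])
  expect_error(fit_components(off, db, 1), class = "rpdlf_value_error")
})

test_that("profile-likelihood bounds behave like confidence intervals", {
  db <- unit_inhom_db()
  # noiseless self-fit: interval collapses to less than one grid step
  dat <- as_data(db, interpolate_modulation(db, 0.06))
  fit <- confidence_bounds(dat, db, fit_components(dat, db, 1))
  expect_lt(fit$components$upper - fit$components$lower, 0.005)
  expect_gte(fit$components$s, fit$components$lower)
  expect_lte(fit$components$s, fit$components$upper)

  # doubling the noise widens the interval (replicate average)
  base <- integrate_over_rf(unit_cond(0.06), unit_rf(), 32)$amplitude
  width <- function(sigma, seed) {
    set.seed(seed)
    mean(replicate(8, {
      y <- base
      y[-1] <- y[-1] + rnorm(31, 0, sigma)
      dat <- as_data(db, y)
      f <- confidence_bounds(dat, db, fit_components(dat, db, 1))
      f$components$upper - f$components$lower
    }))
  }
  expect_lt(width(0.02, 7), width(0.04, 7))
})
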