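test_that("measured T, R, S converge to analytic values on noiseless profiles", {
  m <- fig2_model(1.8)
  pr <- simulate_profile(m, spacing = fwhm(m) / 50, noise_sd = 0)
  meas <- lat50_measure(pr, m$bmd_ref)
  am <- analytic_measurement(m)
  expect_lt(abs(meas$T - am$T), 1e-3)
  expect_lt(abs(meas$R - am$R), 1e-3)
  expect_lt(abs(meas$S - am$S), 1e-3)
  expect_lt(abs(meas$t_minus - am$t_minus), 5e-3)
  expect_lt(abs(meas$t_plus - am$t_plus), 5e-3)
})

test_that("bmc50 agrees with the closed-form area between the crossings", {
  m <- fig2_model(2.5)
  pr <- simulate_profile(m, spacing = fwhm(m) / 80, noise_sd = 0)
  meas <- lat50_measure(pr, m$bmd_ref)
  expect_lt(abs(meas$bmc50_meas /
                  profile_auc(m, meas$t_minus, meas$t_plus) - 1), 1e-4)
})

test_that("symmetric profiles give symmetric crossings", {
  m <- cortex_model(a = 1.4, sigma = 1.2, bmd_ref = 900, b = 80, c = 80)
  pr <- simulate_profile(m, spacing = fwhm(m) / 60, noise_sd = 0)
  meas <- lat50_measure(pr, m$bmd_ref)
  expect_lt(abs(meas$t_minus + meas$t_plus), 1e-9)
})

test_that("LAT50 always overestimates on noiseless profiles; thick limit exact", {
  sigma <- 1.5
  for (a in seq(0.5, 7, length.out = 12) * sigma) {
    m <- fig2_model(a)
    am <- analytic_measurement(m)
    expect_gt(am$a50, m$a)
  }
  # thick cortex: overshoot below 5% of FWHM
  m_thick <- fig2_model(3.5 * sigma)
  am <- analytic_measurement(m_thick)
  expect_lt(am$a50 - m_thick$a, 0.05 * fwhm(m_thick))
  # very thick limit: crossings computed directly on the analytic profile
  # (the normalized route is unusable here: T rounds to 1 in double precision)
  m10 <- fig2_model(10 * sigma)
  pk <- profile_value(m10, 0)
  t_lo <- stats::uniroot(function(t) profile_value(m10, t) - (pk + m10$b) / 2,
                         c(-m10$a - 5 * sigma, 0), tol = 1e-12)$root
  t_hi <- stats::uniroot(function(t) profile_value(m10, t) - (pk + m10$c) / 2,
                         c(0, m10$a + 5 * sigma), tol = 1e-12)$root
  expect_lt(abs((t_hi - t_lo) / 2 / m10$a - 1), 1e-6)
  # thin cortex: substantial overestimation (2a/FWHM = 0.5)
  m_thin <- fig2_model(0.25 * fwhm(fig2_model(1)))
  am_thin <- analytic_measurement(m_thin)
  expect_gt(am_thin$a50 / m_thin$a, 1.5)
})

test_that("a50 is monotone in the true half-thickness", {
  sigma <- 1.5
  a50 <- vapply(seq(0.5, 7, length.out = 14) * sigma,
                function(a) analytic_measurement(fig2_model(a))$a50,
                numeric(1))
  expect_true(all(diff(a50) > 0))
})

test_that("lat50_thickness returns the crossing distance", {
  m <- fig2_model(2)
  am <- analytic_measurement(m)
  am$t_minus <- -1; am$t_plus <- 1
  expect_equal(lat50_thickness(am)$thickness, 2.0)
})

test_that("reflected profiles are measured in canonical orientation", {
  m <- cortex_model(a = 1.5, sigma = 1.2, bmd_ref = 900, b = 30, c = 250)
  pr <- simulate_profile(m, spacing = fwhm(m) / 40, noise_sd = 0)
  flipped <- sampled_profile(rev(-pr$positions), rev(pr$values))
  meas <- lat50_measure(flipped, 900)
  expect_true(meas$reflected)
  ref <- lat50_measure(pr, 900)
  expect_equal(meas$a50, ref$a50, tolerance = 1e-9)
  expect_equal(meas$c_meas, ref$c_meas, tolerance = 1e-9)
})

test_that("degenerate and flat profiles raise informative errors", {
  flat <- sampled_profile(seq(0, 3, length.out = 32), rep(5, 32) + 1e-9 * (1:32))
  expect_error(lat50_measure(flat, 800), "degenerate|crossing")
  m <- fig2_model(1.5)
  pr <- simulate_profile(m, spacing = fwhm(m) / 40)
  expect_error(lat50_measure(pr, 800, tail_fraction = 0.5), "tail_fraction")
  expect_error(lat50_measure(pr, 800, smooth_window = 4L), "odd")
})

test_that("smoothing lowers the measured maximum (documented bias)", {
  m <- fig2_model(0.9)
  pr <- simulate_profile(m, spacing = fwhm(m) / 20, noise_sd = 0)
  raw <- lat50_measure(pr, 800)
  sm <- lat50_measure(pr, 800, smooth_window = 5L)
  expect_lt(sm$bmd_max, raw$bmd_max)
})
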