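test_that("solve_abar reduces to the closed form in the symmetric case", {
  # equal backgrounds: k = 0 and abar = erfinv((T - R) / (1 - R))
  for (R in c(0, 0.2, 0.4)) {
    for (T in c(R + 0.1, R + 0.3, 0.9)) {
      ab <- solve_abar(T, R, S = R)
      expect_equal(ab, erfinv((T - R) / (1 - R)), tolerance = 1e-9)
    }
  }
})

test_that("solve_abar round trip recovers a / (sqrt(2) sigma)", {
  m <- cortex_model(a = 1.2, sigma = 1.5, bmd_ref = 800, b = 0, c = 150)
  am <- analytic_measurement(m)
  ab <- solve_abar(am$T, am$R, am$S)
  expect_equal(ab, m$a / (sqrt(2) * m$sigma), tolerance = 1e-8)
})

test_that("solve_abar limit behaviour and domain errors", {
  R <- 0.2
  # T -> R+ drives abar -> 0; T -> 1- diverges monotonically
  abs_seq <- vapply(c(0.21, 0.25, 0.5, 0.9, 0.99, 0.999),
                    function(T) solve_abar(T, R), numeric(1))
  expect_true(all(diff(abs_seq) > 0))
  expect_lt(abs_seq[1], 0.1)
  expect_gt(abs_seq[length(abs_seq)], 2)
  expect_error(solve_abar(1.01, 0.2), class = "cortiprof_singular")
  expect_error(solve_abar(0.1, 0.2), "T > R")
  expect_error(solve_abar(0.5, 0.1, S = 0.2), "R >= S")
})

test_that("peak equation residual is strictly increasing in abar", {
  for (s in 1:6) {
    set.seed(500 + s)
    S <- runif(1, 0, 0.3); R <- runif(1, S, 0.5); T <- runif(1, R + 0.05, 0.98)
    k <- -0.25 * log((1 - R) / (1 - S))
    g <- function(ab) (1 - S) * erf(k / ab + ab) +
      (R - 1) * erf(k / ab - ab) - 2 * T + S + R
    ab_grid <- seq(0.05, 5, length.out = 60)
    expect_true(all(diff(g(ab_grid)) > 0))
  }
})

test_that("solve_t50 symmetry, round trip, thick limit", {
  # symmetric: t1 = -t2
  ab <- solve_abar(0.7, 0.2, S = 0.2)
  t1 <- solve_t50(0.7, 0.2, 0.2, ab, "low")
  t2 <- solve_t50(0.7, 0.2, 0.2, ab, "high")
  expect_lt(abs(t1 + t2), 1e-9)
  # round trip against measured crossings of a dense noiseless profile
  m <- fig2_model(1.8)
  pr <- simulate_profile(m, spacing = fwhm(m) / 100, noise_sd = 0)
  meas <- lat50_measure(pr, 800)
  sol <- mpa_solve(meas$T, meas$R, meas$S)
  s2s <- sqrt(2) * m$sigma
  expect_lt(abs(sol$t1_bar - meas$t_minus / s2s), 1e-4 + 1e-3)
  expect_lt(abs(sol$t2_bar - meas$t_plus / s2s), 1e-4 + 1e-3)
  # thick cortex: the right 50% point sits at the box edge
  mth <- cortex_model(a = 5 * sqrt(2), sigma = 1, bmd_ref = 1000)
  am <- analytic_measurement(mth)   # abar = 5, R = S = 0
  sol5 <- mpa_solve(am$T, 0, 0)
  expect_lt(abs(sol5$t2_bar - sol5$abar), 0.01)
})

test_that("K: thick limit, quadrature oracle, invariances", {
  # thick limit: K -> 1 from below, with the per-edge tail loss giving
  # 1 - K = 1/(2 sqrt(pi) abar) exactly when R = S = 0 (the 50% points sit
  # at the box edges, each edge blurs sigma/sqrt(2 pi) of mass outside)
  for (ab in c(3, 4, 5)) {
    K <- mpa_solve(erf(ab), 0, 0)$K
    expect_lt(abs((1 - K) - 1 / (2 * sqrt(pi) * ab)), 1e-3)
  }
  expect_gt(mpa_solve(erf(5), 0, 0)$K, mpa_solve(erf(3), 0, 0)$K)
  # K equals AUC(t1,t2) / (2 a B) on the matching dimensional model
  for (s in 1:4) {
    mod <- rand_model(600 + s)
    am <- analytic_measurement(mod)
    sol <- mpa_solve(am$T, am$R, am$S)
    K_quad <- auc_oracle(mod, am$t_minus, am$t_plus, step = fwhm(mod) / 400) /
      (2 * mod$a * mod$bmd_ref)
    expect_lt(abs(sol$K / K_quad - 1), 1e-5)
  }
  # K depends only on (T, R, S): rescaling the density leaves it unchanged
  sol1 <- mpa_solve(0.62, 0.19, 0.01)
  expect_identical(sol1$K, mpa_solve(0.62, 0.19, 0.01)$K)
  # thin cortex undercounts mass: K < 1
  thin <- analytic_measurement(cortex_model(a = 0.5 * sqrt(2) * 1.0,
                                            sigma = 1, bmd_ref = 1000))
  expect_lt(mpa_solve(thin$T, 0, 0)$K, 1)
})

test_that("MPA is exact on its own model across the thickness sweep", {
  sigma <- 1.5
  for (a in seq(0.5, 7, length.out = 10) * sigma) {
    m <- fig2_model(a)
    am <- analytic_measurement(m)
    est <- mpa_thickness(am, m$bmd_ref)
    expect_lt(abs(est$thickness / (2 * a) - 1), 1e-6)
    expect_equal(est$bmc_cort, est$thickness * m$bmd_ref, tolerance = 1e-9)
  }
})

test_that("MPA responds to inputs as the closed form dictates", {
  m <- fig2_model(0.9)
  am <- analytic_measurement(m)
  # doubling the measured mass doubles the thickness (T, R, S fixed)
  am2 <- am; am2$bmc50_meas <- 2 * am$bmc50_meas
  expect_equal(mpa_thickness(am2, 800)$thickness,
               2 * mpa_thickness(am, 800)$thickness, tolerance = 1e-12)
  # underestimated reference density on a thin cortex overestimates thickness
  est_lo <- mpa_thickness(am, 800 * 0.9, regularize = TRUE)
  expect_gt(est_lo$thickness, 2 * m$a)
  # scale invariance: profile and reference scaled together
  ms <- cortex_model(a = m$a, sigma = m$sigma, bmd_ref = 1600, b = 0, c = 300)
  ams <- analytic_measurement(ms)
  expect_equal(mpa_thickness(ams, 1600)$thickness,
               mpa_thickness(am, 800)$thickness, tolerance = 1e-9)
})

test_that("singularity handling in mpa_thickness", {
  m <- fig2_model(6)
  am <- analytic_measurement(m)
  expect_error(mpa_thickness(am, bmd_ref = am$bmd_max * 0.99),
               class = "cortiprof_singular")
  est <- mpa_thickness(am, bmd_ref = am$bmd_max * 0.99, regularize = TRUE)
  expect_true(est$regularized)
  expect_true(is.finite(est$thickness))
})
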