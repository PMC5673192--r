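# Operating point used in several blocks: reference density 1000, R = 1/3,
# sigma = 1, soft tissue 0, at a requested normalized half-thickness.
sense_meas <- function(abar, bmd_ref = 1000, R = 1 / 3, sigma = 1) {
  m <- cortex_model(a = abar * sqrt(2) * sigma, sigma = sigma,
                    bmd_ref = bmd_ref, b = 0, c = R * bmd_ref)
  analytic_measurement(m)
}

test_that("analytic K derivatives match the finite-difference oracle", {
  pts <- list(c(T = 0.5, R = 0.2, S = 0.0),
              c(T = 0.75, R = 1 / 3, S = 0.0),
              c(T = 0.62, R = 0.19, S = 0.05),
              c(T = 0.9, R = 0.15, S = 0.1))
  for (p in pts) {
    kd <- k_derivatives(p["T"], p["R"], p["S"], bmd_ref = 1000)
    fd_T <- richardson_fd(function(x) mpa_solve(x, p["R"], p["S"])$K, p["T"])
    fd_R <- richardson_fd(function(x) mpa_solve(p["T"], x, p["S"])$K, p["R"])
    fd_S <- richardson_fd(function(x) mpa_solve(p["T"], p["R"], x)$K,
                          p["S"] + 1e-4)
    expect_lt(abs(kd$dK_dT / fd_T - 1), 1e-4)
    expect_lt(abs(kd$dK_dR / fd_R - 1), 1e-4)
    # S derivative compared at a nudged point to stay inside the domain
    kd_s <- k_derivatives(p["T"], p["R"], p["S"] + 1e-4, bmd_ref = 1000)
    expect_lt(abs(kd_s$dK_dS / fd_S - 1), 1e-3)
    h <- 1e-4
    fd_TT <- (mpa_solve(p["T"] + h, p["R"], p["S"])$K - 2 * kd$K +
                mpa_solve(p["T"] - h, p["R"], p["S"])$K) / h^2
    expect_lt(abs(kd$d2K_dT2 / fd_TT - 1), 1e-4)
    # chained reference-density derivative: K(bmd_max/B, c/B, b/B)
    B <- 1000
    fd_B <- richardson_fd(function(x) mpa_solve(p["T"] * B / x, p["R"] * B / x,
                                                p["S"] * B / x)$K, B, h = 1e-2)
    expect_lt(abs(kd$dK_dBMDref / fd_B - 1), 1e-4)
  }
})

test_that("near-singular points are refused with guidance", {
  expect_error(k_derivatives(0.9995, 0.2, 0), "lat50_sensitivity|singular")
})

test_that("taylor_delta_a structural identities", {
  am <- sense_meas(1.0)
  rep0 <- taylor_delta_a(am, 1000)
  expect_equal(rep0$predicted_delta_a, 0)
  # the mass term is exact: delta a = dBMC / (2 B K)
  repb <- taylor_delta_a(am, 1000, d_bmc = 37)
  expect_equal(repb$predicted_delta_a, 37 / (2 * 1000 * repb$K),
               tolerance = 1e-12)
  expect_equal(repb$predicted_delta_a,
               sensitivity_fd(am, 1000, d_bmc = 37), tolerance = 1e-9)
  expect_equal(rep0$d_a_dBMC, 1 / (2 * 1000 * rep0$K), tolerance = 1e-12)
})

test_that("Taylor prediction converges at the expected order", {
  am <- sense_meas(0.5)
  hs <- 0.02 / 2^(0:3)
  rem_lin <- rem_quad <- numeric(length(hs))
  for (i in seq_along(hs)) {
    true_d <- sensitivity_fd(am, 1000, d_T = hs[i])
    rep <- taylor_delta_a(am, 1000, d_T = hs[i])
    rem_quad[i] <- abs(rep$predicted_delta_a - true_d)
    rem_lin[i] <- abs(rep$predicted_delta_a -
                        0.5 * rep$d2_a_dT2 * hs[i]^2 - true_d)
  }
  order_lin <- mean(log2(rem_lin[-length(hs)] / rem_lin[-1]))
  order_quad <- mean(log2(rem_quad[-length(hs)] / rem_quad[-1]))
  expect_gt(order_lin, 1.9)   # linear terms leave an O(h^2) remainder
  expect_gt(order_quad, 2.7)  # with the T^2 term the remainder is O(h^3)
})

test_that("full reference-density derivative matches the pipeline oracle", {
  am <- sense_meas(1.25)
  rep <- taylor_delta_a(am, 1000)
  h <- 0.05
  fd <- richardson_fd(function(B) mpa_thickness(am, B)$half_thickness, 1000,
                      h = h)
  expect_lt(abs(rep$d_a_dBMDref / fd - 1), 1e-3)
})

test_that("Taylor fails for thick cortex far from the expansion point", {
  # at abar = 3.5 the operating point sits inside the singular guard band
  # (1 - T ~ 6e-7): the default refuses with guidance ...
  am <- sense_meas(3.5)
  expect_error(taylor_delta_a(am, 1000, d_T = -0.01), "lat50_sensitivity")
  # ... and overriding the guard shows the expansion genuinely diverging
  d <- -0.04 * (am$bmd_max / 1000)          # moderate negative T error
  true_d <- sensitivity_fd(am, 1000, d_T = d)
  pred <- taylor_delta_a(am, 1000, d_T = d,
                         eps_guard = 1e-9)$predicted_delta_a
  expect_gt(abs(pred - true_d) / abs(true_d), 0.5)  # divergence regime
  # ... while the thin cortex tracks closely at the same relative error
  am_thin <- sense_meas(0.5)
  d2 <- -0.04 * (am_thin$bmd_max / 1000)
  true2 <- sensitivity_fd(am_thin, 1000, d_T = d2)
  pred2 <- taylor_delta_a(am_thin, 1000, d_T = d2)$predicted_delta_a
  expect_lt(abs(pred2 - true2) / abs(true2), 0.05)
})

test_that("LAT50 sensitivity matches implicit-crossing recomputation", {
  am <- sense_meas(1.0)
  sens <- lat50_sensitivity(am, 1000)
  # oracle: re-solve the crossings with perturbed (T, R) at fixed geometry
  sigma <- 1; s2s <- sqrt(2) * sigma
  ab <- 1.0   # true normalized half-thickness of this operating point
  a50_of <- function(T, R) {
    t1 <- solve_t50(T, R, 0, ab, "low")
    t2 <- solve_t50(T, R, 0, ab, "high")
    s2s * (t2 - t1) / 2
  }
  T0 <- am$T; R0 <- am$R
  fd_T <- richardson_fd(function(x) a50_of(x, R0), T0, h = 1e-6)
  fd_R <- richardson_fd(function(x) a50_of(T0, x), R0, h = 1e-6)
  expect_lt(abs(sens$d_a50_dT / fd_T - 1), 1e-3)
  expect_lt(abs(sens$d_a50_dR / fd_R - 1), 1e-3)
  # thick cortex: crossings on steep flanks, small sensitivity to T
  thick <- lat50_sensitivity(sense_meas(3.5), 1000)
  expect_lt(abs(thick$d_a50_dT), abs(sens$d_a50_dT))
})
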