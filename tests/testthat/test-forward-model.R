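test_that("profile_value matches erf limits and symmetry", {
  m <- cortex_model(a = 1, sigma = 1.2, bmd_ref = 900, b = 40, c = 200)
  expect_equal(profile_value(m, -1e4), m$b, tolerance = 1e-12)
  expect_equal(profile_value(m, 1e4), m$c, tolerance = 1e-12)
  m0 <- cortex_model(a = 1, sigma = 1.2, bmd_ref = 900)
  expect_equal(profile_value(m0, 0),
               900 * erf(1 / (sqrt(2) * 1.2)), tolerance = 1e-12)
  # even profile when backgrounds match
  mb <- cortex_model(a = 0.8, sigma = 1, bmd_ref = 700, b = 100, c = 100)
  tt <- seq(-4, 4, by = 0.37)
  expect_equal(profile_value(mb, tt), profile_value(mb, -tt), tolerance = 1e-12)
})

test_that("profile_value equals numerical convolution of the boxes", {
  m <- cortex_model(a = 0.75, sigma = 1.5, bmd_ref = 800, b = 0, c = 150)
  expect_lt(abs(profile_value(m, 0.3) - conv_oracle(m, 0.3)), 1e-6)
  for (s in 1:5) {
    mod <- rand_model(100 + s)
    ts <- c(-mod$a, 0, mod$a / 2, mod$a + mod$sigma, 3 * mod$sigma)
    for (t in ts)
      expect_lt(abs(profile_value(mod, t) - conv_oracle(mod, t)), 1e-6)
  }
})

test_that("profile is bounded between backgrounds and reference density", {
  for (s in 1:8) {
    mod <- rand_model(200 + s)
    tt <- seq(-mod$a - 6 * mod$sigma, mod$a + 6 * mod$sigma, length.out = 400)
    p <- profile_value(mod, tt)
    expect_true(all(p > min(mod$b, mod$c) - 1e-9))
    expect_true(all(p < mod$bmd_ref))
  }
})

test_that("canonical orientation is enforced at construction", {
  m <- cortex_model(a = 1, sigma = 1, bmd_ref = 800, b = 300, c = 100)
  expect_true(m$reflected)
  expect_gte(m$c, m$b)
  expect_error(cortex_model(a = -1, sigma = 1, bmd_ref = 800), "a")
  expect_error(cortex_model(a = 1, sigma = 1, bmd_ref = 100, c = 200),
               "bmd_ref")
})

test_that("profile_auc matches quadrature and is additive", {
  m <- cortex_model(a = 0.75, sigma = 1.5, bmd_ref = 800, b = 0, c = 150)
  expect_identical(profile_auc(m, 1, 1), 0)
  for (s in 1:5) {
    mod <- rand_model(300 + s)
    t1 <- -mod$a - runif(1, 0, 3) * mod$sigma
    t2 <- mod$a + runif(1, 0, 3) * mod$sigma
    q <- auc_oracle(mod, t1, t2)
    expect_lt(abs(profile_auc(mod, t1, t2) / q - 1), 1e-5)
    t_mid <- (t1 + t2) / 3
    expect_equal(profile_auc(mod, t1, t_mid) + profile_auc(mod, t_mid, t2),
                 profile_auc(mod, t1, t2), tolerance = 1e-9)
  }
  expect_error(profile_auc(m, 2, 1), "t1")
})

test_that("blurring preserves total cortical mass", {
  m <- cortex_model(a = 1.2, sigma = 1.5, bmd_ref = 800)
  L <- m$a + 12 * m$sigma
  expect_equal(profile_auc(m, -L, L), 2 * m$a * m$bmd_ref, tolerance = 1e-6)
})

test_that("peak location satisfies the closed-form offset relation", {
  for (s in 1:6) {
    mod <- rand_model(400 + s)
    B <- mod$bmd_ref
    k <- -0.25 * log((B - mod$c) / (B - mod$b))
    abar <- mod$a / (sqrt(2) * mod$sigma)
    t_pred <- sqrt(2) * mod$sigma * k / abar
    grid <- seq(t_pred - 2 * mod$sigma, t_pred + 2 * mod$sigma,
                length.out = 8001)
    t_grid <- grid[which.max(profile_value(mod, grid))]
    expect_lt(abs(t_pred - t_grid), grid[2] - grid[1] + 1e-12)
  }
  # zero offset when backgrounds are equal
  mb <- cortex_model(a = 1, sigma = 1, bmd_ref = 700, b = 120, c = 120)
  expect_equal(-0.25 * log((700 - 120) / (700 - 120)), 0)
  g <- seq(-2, 2, length.out = 4001)
  expect_lt(abs(g[which.max(profile_value(mb, g))]), g[2] - g[1] + 1e-12)
})

test_that("simulate_profile is deterministic and noiseless when asked", {
  m <- fig2_model(1.2)
  p0 <- simulate_profile(m, noise_sd = 0)
  expect_equal(p0$values, profile_value(m, p0$positions), tolerance = 0)
  p1 <- simulate_profile(m, noise_sd = 30, seed = 11L)
  p2 <- simulate_profile(m, noise_sd = 30, seed = 11L)
  expect_identical(p1$values, p2$values)
  p3 <- simulate_profile(m, noise_sd = 30, seed = 12L)
  expect_false(identical(p1$values, p3$values))
  # the global RNG stream is not consumed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_profile(m, noise_sd = 30, seed = 5L))
  expect_identical(rnorm(1), before)
})

test_that("short grids are flagged, degenerate grids rejected", {
  m <- fig2_model(1.2)
  expect_warning(p <- simulate_profile(m, half_length = m$a + fwhm(m)),
                 "tails")
  expect_true(p$short_tails)
  expect_error(sampled_profile(1:10, 1:10), "16")
  expect_error(sampled_profile(c(1:16) * c(1, 1.5)[c(1, rep(2, 15))],
                               rnorm(16)), "uniform|increasing")
})
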