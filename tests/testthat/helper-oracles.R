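# Independent numerical oracles used across the suite. These deliberately
# avoid the closed forms they check: the convolution oracle integrates the
# Gaussian against the raw box functions by piecewise trapezoid (with the
# box discontinuities as panel breaks, so the integrand is smooth on every
# panel), and the area oracle is plain trapezoidal quadrature of the
# profile values.

# numeric convolution of G_sigma with the three-box cortex at position t
conv_oracle <- function(model, t, step = fwhm(model) / 500) {
  g <- function(u) stats::dnorm(u, mean = 0, sd = model$sigma)
  L <- model$a + 10 * model$sigma
  # integrate g(t - u) * height over u in [u1, u2] by composite Simpson
  piece <- function(u1, u2, height) {
    if (height == 0 || u2 <= u1) return(0)
    n <- max(8L, 2L * ceiling((u2 - u1) / step / 2))
    u <- seq(u1, u2, length.out = n + 1L)
    y <- g(t - u) * height
    h <- (u2 - u1) / n
    w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
    h / 3 * sum(w * y)
  }
  piece(-L, -model$a, model$b) +
    piece(-model$a, model$a, model$bmd_ref) +
    piece(model$a, L, model$c)
}

# trapezoidal area of sampled values
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# trapezoid quadrature of the analytic profile between t1 and t2
auc_oracle <- function(model, t1, t2, step = fwhm(model) / 200) {
  x <- seq(t1, t2, length.out = max(16L, ceiling((t2 - t1) / step)) + 1L)
  trapz(x, profile_value(model, x))
}

# random valid cortex model under a fixed seed offset
rand_model <- function(seed) {
  set.seed(seed)
  sigma <- runif(1, 0.5, 2.5)
  a <- runif(1, 0.4, 6) * sigma
  bmd_ref <- runif(1, 500, 1500)
  c <- runif(1, 0, 0.5) * bmd_ref
  b <- runif(1, 0, c)
  cortex_model(a = a, sigma = sigma, bmd_ref = bmd_ref, b = b, c = c)
}

# Richardson-extrapolated central difference of f at x
richardson_fd <- function(f, x, h = 1e-5) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# Fig 2 style simulation model used in several places
fig2_model <- function(a) cortex_model(a = a, sigma = 1.5, bmd_ref = 800,
                                       b = 0, c = 150)

# sensitivity operating point (reference density 1000, R = 1/3, sigma = 1)
sense_meas_acc <- function(abar, bmd_ref = 1000, R = 1 / 3, sigma = 1) {
  analytic_measurement(cortex_model(a = abar * sqrt(2) * sigma, sigma = sigma,
                                    bmd_ref = bmd_ref, b = 0,
                                    c = R * bmd_ref))
}
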