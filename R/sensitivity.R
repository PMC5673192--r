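#' Analytic derivatives of the correction factor K
#'
#' Partial derivatives of `K(T, R, S)` (and the chained derivative with
#' respect to the reference density, holding the raw `bmd_max`, `c`, `b`
#' fixed), obtained by implicit differentiation through the peak equation
#' and the two 50%-point equations, plus the second derivative in `T`. All
#' expressions are closed-form; the package test suite validates every one
#' against Richardson-extrapolated central differences of [mpa_solve()].
#'
#' Near the singular level `T = 1` the solution degenerates (`abar` diverges)
#' and the Taylor error model is useless; inside a guard band
#' `1 - T < eps_guard` the function refuses with guidance to use the LAT50
#' sensitivity instead.
#'
#' @inheritParams solve_abar
#' @param bmd_ref optional reference density; when given, the chained
#'   `dK/dBMD_ref = -(T K_T + R K_R + S K_S) / bmd_ref` is also returned.
#' @param eps_guard near-singular guard band on `1 - T`.
#' @return a list with `K`, `dK_dT`, `dK_dR`, `dK_dS`, `dK_dBMDref`,
#'   `d2K_dT2`, and the underlying `solution`.
#' @export
k_derivatives <- function(T, R, S = 0, bmd_ref = NULL, eps_guard = 1e-3) {
  .check_trs(T, R, S)
  if (1 - T < eps_guard)
    stop("k_derivatives: T within ", eps_guard, " of the singular level 1; ",
         "the Taylor model is unusable here - use lat50_sensitivity()")
  sol <- mpa_solve(T, R, S)
  ab <- sol$abar; t1 <- sol$t1_bar; t2 <- sol$t2_bar
  k <- sol$k
  k_R <- 1 / (4 * (1 - R))
  k_S <- -1 / (4 * (1 - S))
  phi <- erf_deriv                       # erf'
  dphi <- function(x) -2 * x * phi(x)    # erf''

  ## --- peak equation g(abar; T, R, S) = 0 ---------------------------------
  u <- k / ab + ab;  v <- k / ab - ab
  u_a <- 1 - k / ab^2; v_a <- -k / ab^2 - 1
  u_aa <- 2 * k / ab^3; v_aa <- 2 * k / ab^3
  g_a <- (1 - S) * phi(u) * u_a + (R - 1) * phi(v) * v_a
  g_aa <- (1 - S) * (dphi(u) * u_a^2 + phi(u) * u_aa) +
    (R - 1) * (dphi(v) * v_a^2 + phi(v) * v_aa)
  a_T <- 2 / g_a
  a_TT <- -4 * g_aa / g_a^3
  g_R <- (1 - S) * phi(u) * (k_R / ab) + erf(v) +
    (R - 1) * phi(v) * (k_R / ab) + 1
  a_R <- -g_R / g_a
  g_S <- -erf(u) + (1 - S) * phi(u) * (k_S / ab) +
    (R - 1) * phi(v) * (k_S / ab) + 1
  a_S <- -g_S / g_a

  ## --- 50%-point equations ------------------------------------------------
  # h(t, abar) = (1-S) erf(t+abar) + (R-1) erf(t-abar) - T + {R or S}
  cross <- function(t, rhs_dR, rhs_dS) {
    p <- phi(t + ab); q <- phi(t - ab)
    dp <- dphi(t + ab); dq <- dphi(t - ab)
    h_t <- (1 - S) * p + (R - 1) * q
    h_a <- (1 - S) * p - (R - 1) * q
    h_tt <- (1 - S) * dp + (R - 1) * dq
    h_ta <- (1 - S) * dp - (R - 1) * dq
    t_T <- (1 - h_a * a_T) / h_t
    t_TT <- -(h_tt * t_T^2 + 2 * h_ta * t_T * a_T + h_tt * a_T^2 +
                h_a * a_TT) / h_t
    t_R <- -(h_a * a_R + rhs_dR) / h_t
    t_S <- -(h_a * a_S + rhs_dS) / h_t
    list(T = t_T, TT = t_TT, R = t_R, S = t_S)
  }
  d1 <- cross(t1, rhs_dR = erf(t1 - ab) + 1, rhs_dS = -erf(t1 + ab))
  d2 <- cross(t2, rhs_dR = erf(t2 - ab),     rhs_dS = -erf(t2 + ab) + 1)

  ## --- explicit partials of A(abar, t1, t2; R, S), K = A / (4 abar) -------
  E <- erf
  A <- 4 * ab * sol$K
  A_t1 <- -E(t1 + ab) + E(t1 - ab) + R * (-1 - E(t1 - ab)) +
    S * (-1 + E(t1 + ab))
  A_t2 <- E(t2 + ab) - E(t2 - ab) + R * (1 + E(t2 - ab)) +
    S * (1 - E(t2 + ab))
  A_a <- (E(t2 + ab) - E(t1 + ab) + E(t2 - ab) - E(t1 - ab)) +
    R * (-E(t2 - ab) + E(t1 - ab)) + S * (-E(t2 + ab) + E(t1 + ab))
  A_R <- t2 - t1 + er(t2 - ab) - er(t1 - ab)
  A_S <- t2 - t1 - er(t2 + ab) + er(t1 + ab)
  A_t1t1 <- -(1 - S) * phi(t1 + ab) + (1 - R) * phi(t1 - ab)
  A_t2t2 <- (1 - S) * phi(t2 + ab) - (1 - R) * phi(t2 - ab)
  A_t1a <- -(1 - S) * phi(t1 + ab) - (1 - R) * phi(t1 - ab)
  A_t2a <- (1 - S) * phi(t2 + ab) + (1 - R) * phi(t2 - ab)
  A_aa <- (1 - S) * (phi(t2 + ab) - phi(t1 + ab)) -
    (1 - R) * (phi(t2 - ab) - phi(t1 - ab))

  F_T <- A_a * a_T + A_t1 * d1$T + A_t2 * d2$T
  F_R <- A_a * a_R + A_t1 * d1$R + A_t2 * d2$R + A_R
  F_S <- A_a * a_S + A_t1 * d1$S + A_t2 * d2$S + A_S
  F_TT <- A_aa * a_T^2 + A_t1t1 * d1$T^2 + A_t2t2 * d2$T^2 +
    2 * A_t1a * a_T * d1$T + 2 * A_t2a * a_T * d2$T +
    A_a * a_TT + A_t1 * d1$TT + A_t2 * d2$TT

  K <- sol$K
  K_T <- F_T / (4 * ab) - K * a_T / ab
  K_R <- F_R / (4 * ab) - K * a_R / ab
  K_S <- F_S / (4 * ab) - K * a_S / ab
  K_TT <- F_TT / (4 * ab) - (2 * F_T * a_T + A * a_TT) / (4 * ab^2) +
    A * a_T^2 / (2 * ab^3)

  dK_dB <- if (is.null(bmd_ref)) NA_real_ else
    -(T * K_T + R * K_R + S * K_S) / bmd_ref
  list(K = K, dK_dT = K_T, dK_dR = K_R, dK_dS = K_S,
       dK_dBMDref = dK_dB, d2K_dT2 = K_TT, solution = sol)
}

#' Taylor error propagation for the MPA thickness
#'
#' First-order propagation of measurement errors in the 50%-interval mass,
#' the normalized maximum `T`, the normalized trabecular density `R`, and the
#' reference density into the half-thickness, with the second-order `T` term
#' included (the 50%-point position is not monotone in `T`, so the curvature
#' matters there); mixed second-order terms are deliberately omitted:
#' \deqn{\Delta a \approx \frac{\Delta BMC}{2BK}
#'  - \frac{BMC}{2B}\Big(\frac{K_T}{K^2}\Delta T + \frac{K_R}{K^2}\Delta R
#'  + \big(\frac{1}{BK} + \frac{K_B}{K^2}\big)\Delta B
#'  - \frac{2K_T^2 - K\,K_{TT}}{2K^3}\Delta T^2\Big).}
#' `Delta T` and `Delta R` are errors in the raw densities divided by the
#' (fixed) reference density; `Delta B` additionally shifts `T` and `R`
#' through the chained `K_B`. Accurate for thin-to-midrange cortices; near
#' the singular level `T -> 1` (thick cortex with underestimated reference)
#' the expansion fails and the function refuses via [k_derivatives()].
#'
#' @inheritParams mpa_thickness
#' @param d_bmc error in the measured 50%-interval mass.
#' @param d_T,d_R errors in `T` and `R` (dimensionless, i.e. density errors
#'   already divided by `bmd_ref`).
#' @param d_bmdref error in the reference density (density units).
#' @param eps_guard near-singular guard band, passed to [k_derivatives()];
#'   lower it only to demonstrate the documented thick-cortex failure.
#' @return an object of class `sensitivity_report` with the individual
#'   derivatives of `a`, the `predicted_delta_a` (mm), and the inputs.
#' @export
taylor_delta_a <- function(m, bmd_ref, d_bmc = 0, d_T = 0, d_R = 0,
                           d_bmdref = 0, eps_guard = 1e-3) {
  stopifnot(inherits(m, "lat50_measurement"), bmd_ref > 0)
  T <- m$bmd_max / bmd_ref
  R <- m$c_meas / bmd_ref
  S <- m$b_meas / bmd_ref
  kd <- k_derivatives(T, R, S, bmd_ref = bmd_ref, eps_guard = eps_guard)
  K <- kd$K
  BMC <- m$bmc50_meas
  B <- bmd_ref
  d_a_dBMC <- 1 / (2 * B * K)
  d_a_dT <- -BMC / (2 * B) * kd$dK_dT / K^2
  d_a_dR <- -BMC / (2 * B) * kd$dK_dR / K^2
  d_a_dB <- -BMC / (2 * B) * (1 / (B * K) + kd$dK_dBMDref / K^2)
  d2_a_dT2 <- BMC / (2 * B) * (2 * kd$dK_dT^2 - K * kd$d2K_dT2) / K^3
  delta <- d_a_dBMC * d_bmc + d_a_dT * d_T + d_a_dR * d_R +
    d_a_dB * d_bmdref + 0.5 * d2_a_dT2 * d_T^2
  structure(
    list(d_a_dBMC = d_a_dBMC, d_a_dT = d_a_dT, d_a_dR = d_a_dR,
         d_a_dBMDref = d_a_dB, d2_a_dT2 = d2_a_dT2,
         predicted_delta_a = delta,
         errors = list(d_bmc = d_bmc, d_T = d_T, d_R = d_R,
                       d_bmdref = d_bmdref),
         K = K, a = BMC / (2 * B * K)),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity_report: a =", format(x$a, digits = 6),
      "mm, K =", format(x$K, digits = 6), "\n")
  cat("  da/dBMC =", format(x$d_a_dBMC, digits = 5),
      "; da/dT =", format(x$d_a_dT, digits = 5),
      "; da/dR =", format(x$d_a_dR, digits = 5), "\n")
  cat("  da/dBMDref =", format(x$d_a_dBMDref, digits = 5),
      "; d2a/dT2 =", format(x$d2_a_dT2, digits = 5), "\n")
  cat("  predicted delta a =", format(x$predicted_delta_a, digits = 6), "mm\n")
  invisible(x)
}

#' Ground-truth error by recomputation
#'
#' The exact thickness error for a given error vector, obtained by rerunning
#' the full MPA solve on the perturbed inputs (`bmd_max + dT * B`,
#' `c + dR * B`, `BMC + dBMC`, `B + dB`) and subtracting the unperturbed
#' half-thickness. This is the independent oracle the Taylor report is
#' validated against.
#'
#' @inheritParams taylor_delta_a
#' @return exact `delta a`, mm.
#' @export
sensitivity_fd <- function(m, bmd_ref, d_bmc = 0, d_T = 0, d_R = 0,
                           d_bmdref = 0) {
  stopifnot(inherits(m, "lat50_measurement"))
  a0 <- mpa_thickness(m, bmd_ref)$half_thickness
  m2 <- m
  m2$bmd_max <- m$bmd_max + d_T * bmd_ref
  m2$c_meas <- m$c_meas + d_R * bmd_ref
  m2$bmc50_meas <- m$bmc50_meas + d_bmc
  a1 <- mpa_thickness(m2, bmd_ref + d_bmdref)$half_thickness
  a1 - a0
}

#' First-order sensitivity of the LAT50 thickness
#'
#' Propagates errors in the normalized maximum (`Delta T`) and trabecular
#' level (`Delta R`) into the 50%-threshold half-thickness by implicit
#' differentiation of the two crossing conditions on the analytic profile,
#' holding the underlying cortex geometry fixed. The profile shape is
#' reconstructed from the measurement itself: the normalized solve yields
#' `abar` and the model-implied PSF width via `sqrt(2) sigma = a_MPA / abar`,
#' which converts normalized crossing shifts to millimetres. Position errors
#' of the 50% points caused by noise between peak and background are not
#' modelled.
#'
#' @inheritParams taylor_delta_a
#' @return a list with the derivatives `d_a50_dT`, `d_a50_dR` (mm per unit)
#'   and `predicted_delta_a50` (mm) for the supplied errors.
#' @export
lat50_sensitivity <- function(m, bmd_ref, d_T = 0, d_R = 0) {
  stopifnot(inherits(m, "lat50_measurement"), bmd_ref > 0)
  T <- m$bmd_max / bmd_ref
  R <- m$c_meas / bmd_ref
  S <- m$b_meas / bmd_ref
  sol <- mpa_solve(T, R, S)
  ab <- sol$abar; t1 <- sol$t1_bar; t2 <- sol$t2_bar
  a_mpa <- m$bmc50_meas / (2 * bmd_ref * sol$K)
  s2sigma <- a_mpa / ab                  # model-implied sqrt(2)*sigma, mm
  phi <- erf_deriv
  f_t1 <- (1 - S) * phi(t1 + ab) + (R - 1) * phi(t1 - ab)   # > 0, rising flank
  f_t2 <- (1 - S) * phi(t2 + ab) + (R - 1) * phi(t2 - ab)   # < 0, falling flank
  t1_T <- 1 / f_t1
  t2_T <- 1 / f_t2
  t1_R <- -(1 + erf(t1 - ab)) / f_t1
  t2_R <- -erf(t2 - ab) / f_t2
  d_a50_dT <- s2sigma * (t2_T - t1_T) / 2
  d_a50_dR <- s2sigma * (t2_R - t1_R) / 2
  list(d_a50_dT = d_a50_dT, d_a50_dR = d_a50_dR,
       predicted_delta_a50 = d_a50_dT * d_T + d_a50_dR * d_R,
       implied_sigma = s2sigma / sqrt(2))
}
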