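#' Solve for the normalized half-thickness
#'
#' Finds the unique root `abar = a / (sqrt(2) * sigma)` of the normalized
#' peak equation
#' \deqn{(1-S)\,\mathrm{erf}(k/\bar a + \bar a) + (R-1)\,\mathrm{erf}(k/\bar a - \bar a)
#'       - 2T + S + R = 0,}
#' where \eqn{k = -\tfrac14 \ln\frac{1-R}{1-S}} locates the profile peak at
#' \eqn{\bar t_{max} = k/\bar a}. The left-hand side is strictly increasing
#' in `abar` with opposite signs at 0 and infinity, so the root is unique;
#' it is bracketed by geometric expansion and refined with Brent's method.
#'
#' Note the PSF width never enters: the solution is purely a function of the
#' normalized measurables (T, R, S).
#'
#' @param T normalized profile maximum `bmd_max / bmd_ref`, in (R, 1).
#' @param R normalized trabecular density `c / bmd_ref`, in \[S, T).
#' @param S normalized soft-tissue density `b / bmd_ref`, in \[0, R\].
#' @param tol residual tolerance on the equation.
#' @return `abar`, dimensionless.
#' @export
solve_abar <- function(T, R, S = 0, tol = 1e-12) {
  .check_trs(T, R, S)
  k <- -0.25 * log((1 - R) / (1 - S))
  g <- function(ab) {
    (1 - S) * erf(k / ab + ab) + (R - 1) * erf(k / ab - ab) - 2 * T + S + R
  }
  lo <- 1e-8
  hi <- 1
  i <- 0L
  while (g(hi) < 0) {
    hi <- hi * 2
    i <- i + 1L
    if (i > 60L) stop("solve_abar: failed to bracket root (T too close to 1?)")
  }
  root <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # polish by bisection until the residual meets `tol`
  a_lo <- max(lo, root * 0.5); a_hi <- min(hi, root * 2)
  while (abs(g(root)) > tol && (a_hi - a_lo) > .Machine$double.eps * root) {
    if (g(root) > 0) a_hi <- root else a_lo <- root
    root <- (a_lo + a_hi) / 2
  }
  root
}

.check_trs <- function(T, R, S) {
  if (!(S >= 0)) stop("invalid parameters: need S >= 0")
  if (!(R >= S)) stop("invalid parameters: need R >= S")
  if (!(T > R)) stop("invalid parameters: need T > R")
  if (!(T < 1))
    stop(errorCondition(
      paste0("singular parameters: T = ", format(T),
             " >= 1 (bmd_max >= bmd_ref); regularize first"),
      class = "cortiprof_singular"))
  invisible(TRUE)
}

#' Solve for a normalized 50% point
#'
#' Given `abar`, solves the crossing equation
#' \deqn{(1-S)\,\mathrm{erf}(\bar t + \bar a) + (R-1)\,\mathrm{erf}(\bar t - \bar a) = T - R}
#' (left, soft-tissue side; `side = "low"`) or `= T - S` (right, trabecular
#' side; `side = "high"`). The left-hand side has a single maximum at
#' \eqn{\bar t_{max} = k/\bar a}; restricting the search to the half-line on
#' the requested side of the peak makes the root unique.
#'
#' @inheritParams solve_abar
#' @param abar normalized half-thickness from [solve_abar()].
#' @param side `"low"` for the left 50% point, `"high"` for the right.
#' @return normalized position `t / (sqrt(2) * sigma)`.
#' @export
solve_t50 <- function(T, R, S = 0, abar, side = c("low", "high"),
                      tol = 1e-12) {
  side <- match.arg(side)
  .check_trs(T, R, S)
  stopifnot(abar > 0)
  k <- -0.25 * log((1 - R) / (1 - S))
  tmax <- k / abar
  target <- if (side == "low") T - R else T - S
  f <- function(t) (1 - S) * erf(t + abar) + (R - 1) * erf(t - abar) - target
  step <- max(abar, 1)
  lim <- 50 * (abar + 1)
  if (side == "low") {
    hi <- tmax
    lo <- tmax - step
    while (f(lo) > 0) {
      lo <- lo - step
      if (tmax - lo > lim) stop("solve_t50: bracket expansion failed (low)")
    }
    interval <- c(lo, hi)
  } else {
    lo <- tmax
    hi <- tmax + step
    while (f(hi) > 0) {
      hi <- hi + step
      if (hi - tmax > lim) stop("solve_t50: bracket expansion failed (high)")
    }
    interval <- c(lo, hi)
  }
  root <- stats::uniroot(f, interval, tol = .Machine$double.eps^0.75)$root
  a_lo <- interval[1]; a_hi <- interval[2]
  sgn <- if (side == "low") 1 else -1  # f increasing left of peak, decreasing right
  while (abs(f(root)) > tol && (a_hi - a_lo) > .Machine$double.eps * (abs(root) + 1)) {
    if (sgn * f(root) > 0) a_hi <- root else a_lo <- root
    root <- (a_lo + a_hi) / 2
  }
  root
}

# Correction factor K = AUC(t1, t2) / (2 a bmd_ref) in normalized variables;
# internal, shared with the sensitivity module.
.k_value <- function(abar, t1, t2, R, S) {
  A <- (er(t2 + abar) - er(t1 + abar) - er(t2 - abar) + er(t1 - abar)) +
    R * (t2 - t1 + er(t2 - abar) - er(t1 - abar)) +
    S * (t2 - t1 - er(t2 + abar) + er(t1 + abar))
  A / (4 * abar)
}

#' Full normalized MPA solution
#'
#' Runs the whole normalized solve: `abar` from the peak equation, both 50%
#' points, and the mass correction factor
#' \deqn{K = \frac{AUC(t_1, t_2)}{2 a\, BMD_{ref}},}
#' evaluated in closed form via the primitive [er()]. `K` depends only on
#' (T, R, S) — neither the PSF width nor the density scale enters — which is
#' what makes a two-entry lookup table possible.
#'
#' @inheritParams solve_abar
#' @return an object of class `normalized_solution` with fields `abar`, `k`,
#'   `tmax_bar`, `t1_bar`, `t2_bar`, `K`.
#' @export
mpa_solve <- function(T, R, S = 0, tol = 1e-12) {
  abar <- solve_abar(T, R, S, tol)
  t1 <- solve_t50(T, R, S, abar, "low", tol)
  t2 <- solve_t50(T, R, S, abar, "high", tol)
  k <- -0.25 * log((1 - R) / (1 - S))
  structure(
    list(abar = abar, k = k, tmax_bar = k / abar,
         t1_bar = t1, t2_bar = t2,
         K = .k_value(abar, t1, t2, R, S),
         T = T, R = R, S = S),
    class = "normalized_solution"
  )
}

#' @export
print.normalized_solution <- function(x, ...) {
  cat("normalized_solution: abar =", format(x$abar, digits = 8),
      ", K =", format(x$K, digits = 8), "\n")
  cat("  tmax_bar =", format(x$tmax_bar, digits = 6),
      "; 50% points [", format(x$t1_bar, digits = 6), ",",
      format(x$t2_bar, digits = 6), "]\n")
  invisible(x)
}

#' MPA thickness estimate
#'
#' Model-based profile analysis: the measured mass between the 50% points is
#' converted to true cortical mass with the correction factor `K(T, R, S)`
#' and then to thickness,
#' \deqn{a = \frac{BMC_{50,meas}}{2\, BMD_{ref}\, K}.}
#' Exact on noiseless model profiles with the true reference density. The
#' PSF width is never required.
#'
#' Normalization happens here, against the `bmd_ref` argument, so reference
#' density misspecification can be studied on a fixed measurement. When noise
#' pushes `bmd_max` to or above `bmd_ref` the parameters are singular
#' (`T >= 1`); with `regularize = TRUE` the measurement maximum is clamped to
#' `(1 - eps) * bmd_ref` (equivalently `T = 1 - eps`) and flagged, otherwise
#' an error of class `cortiprof_singular` is raised.
#'
#' @param m a [lat50_measure()] result.
#' @param bmd_ref assumed reference density.
#' @param lut optional [build_k_lut()] table for the fast path (used only
#'   when `S` is numerically 0, as the table has two entries).
#' @param regularize clamp `T` to `1 - eps` when `T >= 1`.
#' @param eps clamp margin.
#' @return a `thickness_estimate` with `method = "MPA"`; `bmc_cort` equals
#'   `thickness * bmd_ref` by construction.
#' @export
mpa_thickness <- function(m, bmd_ref, lut = NULL, regularize = FALSE,
                          eps = 1e-6) {
  stopifnot(inherits(m, "lat50_measurement"), bmd_ref > 0)
  T <- m$bmd_max / bmd_ref
  R <- m$c_meas / bmd_ref
  S <- m$b_meas / bmd_ref
  flags <- character(0)
  if (S < 0) { S <- 0; flags <- c(flags, "S_clamped_to_zero") }
  if (R < S) { R <- S; flags <- c(flags, "R_raised_to_S") }
  regularized <- FALSE
  if (T >= 1) {
    if (!regularize)
      .check_trs(T, R, S)  # raises cortiprof_singular
    T <- 1 - eps
    regularized <- TRUE
    flags <- c(flags, "T_clamped")
  }
  K <- NULL
  if (!is.null(lut) && S <= 1e-12) {
    K <- lut_K(lut, T, R)
    if (isTRUE(attr(K, "fallback"))) flags <- c(flags, "lut_fallback")
    sol <- NULL
  }
  if (is.null(K)) {
    sol <- mpa_solve(T, R, S)
    K <- sol$K
  }
  a <- m$bmc50_meas / (2 * bmd_ref * as.numeric(K))
  thickness_estimate(
    thickness = 2 * a, method = "MPA", K_used = as.numeric(K),
    bmc_cort = m$bmc50_meas / as.numeric(K), regularized = regularized,
    diagnostics = list(T = T, R = R, S = S, flags = flags, solution = sol)
  )
}

#' Build the K lookup table
#'
#' Precomputes the correction factor `K` on a rectangular (T, R) grid for a
#' fixed `S` (default 0: soft tissue assumed to have zero density, the usual
#' simplification — profiles with `S != 0` bypass the table). Nodes with
#' `T <= R + delta` are infeasible and stored as `NA`. The default grid step
#' keeps the bilinear interpolation error in `K` below 1e-3.
#'
#' @param T_grid,R_grid ascending grids; defaults T 0.02..0.999 step 0.002,
#'   R 0..0.9 step 0.01.
#' @param S_fixed fixed normalized soft-tissue density.
#' @param eps_singular the T grid is truncated below `1 - eps_singular`.
#' @param delta minimal T - R margin for a node to be computed.
#' @return an object of class `k_lut`.
#' @export
build_k_lut <- function(T_grid = seq(0.02, 0.999, by = 0.002),
                        R_grid = seq(0, 0.90, by = 0.01),
                        S_fixed = 0, eps_singular = 1e-4, delta = 1e-4) {
  stopifnot(!is.unsorted(T_grid, strictly = TRUE),
            !is.unsorted(R_grid, strictly = TRUE))
  T_grid <- T_grid[T_grid < 1 - eps_singular]
  K <- matrix(NA_real_, length(T_grid), length(R_grid))
  for (j in seq_along(R_grid)) {
    R <- R_grid[j]
    if (R < S_fixed) next
    for (i in seq_along(T_grid)) {
      T <- T_grid[i]
      if (T <= R + delta) next
      K[i, j] <- mpa_solve(T, R, S_fixed)$K
    }
  }
  structure(
    list(T_grid = T_grid, R_grid = R_grid, K_values = K, S_fixed = S_fixed,
         eps_singular = eps_singular, delta = delta,
         built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         version = as.character(utils::packageVersion("cortiprof"))),
    class = "k_lut"
  )
}

#' @export
print.k_lut <- function(x, ...) {
  cat("k_lut:", length(x$T_grid), "x", length(x$R_grid), "(T x R) nodes,",
      sum(is.finite(x$K_values)), "feasible; S =", x$S_fixed, "\n")
  cat("  T in [", min(x$T_grid), ",", max(x$T_grid), "], R in [",
      min(x$R_grid), ",", max(x$R_grid), "]; built", x$built, "\n")
  invisible(x)
}

#' Interpolate K from a lookup table
#'
#' Bilinear interpolation of the stored correction factor. Queries at grid
#' nodes return the stored value exactly. Queries outside the table hull or
#' in cells with infeasible corners are not extrapolated: the value is
#' computed directly by [mpa_solve()] and the result carries attribute
#' `fallback = TRUE` together with a warning.
#'
#' @param lut a [build_k_lut()] table.
#' @param T,R query point.
#' @return the interpolated `K` (numeric scalar, possibly with attribute
#'   `fallback`).
#' @export
lut_K <- function(lut, T, R) {
  stopifnot(inherits(lut, "k_lut"))
  Tg <- lut$T_grid; Rg <- lut$R_grid
  fallback <- function(why) {
    warning("lut_K: ", why, "; falling back to direct computation")
    out <- mpa_solve(T, R, lut$S_fixed)$K
    attr(out, "fallback") <- TRUE
    out
  }
  if (T < Tg[1] || T > Tg[length(Tg)] || R < Rg[1] || R > Rg[length(Rg)])
    return(fallback("query outside table hull"))
  i <- findInterval(T, Tg, rightmost.closed = TRUE)
  j <- findInterval(R, Rg, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(Tg) - 1L)
  j <- min(max(j, 1L), length(Rg) - 1L)
  corners <- lut$K_values[c(i, i + 1L), c(j, j + 1L)]
  if (any(!is.finite(corners)))
    return(fallback("cell touches infeasible region (T too close to R)"))
  u <- (T - Tg[i]) / (Tg[i + 1L] - Tg[i])
  v <- (R - Rg[j]) / (Rg[j + 1L] - Rg[j])
  (1 - u) * (1 - v) * corners[1, 1] + u * (1 - v) * corners[2, 1] +
    (1 - u) * v * corners[1, 2] + u * v * corners[2, 2]
}

#' Persist / load a K lookup table
#'
#' The table is stored as a single JSON container holding the grids, the
#' value matrix (infeasible nodes as null), and build metadata.
#'
#' @param lut a `k_lut`.
#' @param path file path.
#' @return `read_k_lut()` returns the `k_lut`; `write_k_lut()` returns
#'   `path` invisibly.
#' @export
write_k_lut <- function(lut, path) {
  stopifnot(inherits(lut, "k_lut"))
  obj <- unclass(lut)
  # row-major list of rows; jsonlite writes NA as null
  obj$K_values <- lapply(seq_len(nrow(lut$K_values)),
                         function(i) as.numeric(lut$K_values[i, ]))
  obj$dim <- dim(lut$K_values)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_k_lut
#' @export
read_k_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- obj$K_values
  if (is.list(K))   # rows of unequal simplification: bind manually
    K <- do.call(rbind, lapply(K, function(r) as.numeric(unlist(r))))
  K <- matrix(as.numeric(K), nrow = length(obj$T_grid), byrow = FALSE)
  structure(
    list(T_grid = as.numeric(obj$T_grid), R_grid = as.numeric(obj$R_grid),
         K_values = K, S_fixed = obj$S_fixed,
         eps_singular = obj$eps_singular, delta = obj$delta,
         built = obj$built, version = obj$version),
    class = "k_lut"
  )
}
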