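#' Measure LAT50 parameters of a sampled profile
#'
#' Extracts from a sampled profile the parameter set used by both the local
#' adaptive 50% threshold (LAT50) and the model-based estimators:
#' the profile maximum `bmd_max`, the mean soft-tissue and trabecular
#' background densities `b_meas`/`c_meas` (outer tail windows), the two
#' 50%-crossing positions, the mass between them `bmc50_meas`, and the
#' LAT50 half-thickness `a50 = (t_plus - t_minus) / 2`.
#'
#' The 50% level on each side is halfway between `bmd_max` and that side's
#' background: left level `(bmd_max + b_meas)/2`, right level
#' `(bmd_max + c_meas)/2`. Crossings are located by linear interpolation
#' between adjacent samples, scanning outward from the profile maximum and
#' taking the crossing nearest the peak on each side (conservative against
#' detached noise blobs).
#'
#' The profile is reflected to canonical orientation (denser background on
#' the right) when needed; `reflected` records this. `bmd_ref` is used only
#' to normalize `T = bmd_max/bmd_ref`, `R = c_meas/bmd_ref`,
#' `S = b_meas/bmd_ref`; estimating the reference density itself is out of
#' scope here.
#'
#' @param profile a [sampled_profile()].
#' @param bmd_ref reference (compact cortical) density used for normalization.
#' @param tail_fraction fraction (0, 0.3] of samples on each end averaged for
#'   the background densities; default 0.2.
#' @param smooth_window odd integer width of an optional centred running-mean
#'   filter applied before measuring; 1 (default) disables smoothing. Note
#'   that smoothing lowers `bmd_max` on average and so biases `T` down.
#' @return an object of class `lat50_measurement` with fields `bmd_max`,
#'   `b_meas`, `c_meas`, `T`, `R`, `S`, `t_minus`, `t_plus`, `bmc50_meas`,
#'   `a50`, `bmd_ref`, plus provenance (`tail_fraction`, `smooth_window`,
#'   `spacing`, `reflected`).
#' @seealso [lat50_thickness()], [mpa_thickness()], [hmpa_thickness()]
#' @export
lat50_measure <- function(profile, bmd_ref, tail_fraction = 0.2,
                          smooth_window = 1L) {
  stopifnot(inherits(profile, "sampled_profile"), bmd_ref > 0)
  if (!(tail_fraction > 0 && tail_fraction <= 0.3))
    stop("lat50_measure: tail_fraction must be in (0, 0.3]")
  pos <- profile$positions
  val <- profile$values
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L)
      stop("lat50_measure: smooth_window must be odd")
    sm <- stats::filter(val, rep(1 / smooth_window, smooth_window), sides = 2)
    keep <- !is.na(sm)
    val <- as.numeric(sm[keep])
    pos <- pos[keep]
  }
  n <- length(val)
  ntail <- max(1L, floor(tail_fraction * n))
  left_mean <- mean(val[seq_len(ntail)])
  right_mean <- mean(val[seq.int(n - ntail + 1L, n)])
  reflected <- FALSE
  if (left_mean > right_mean) {  # canonical orientation: denser side right
    pos <- rev(-pos)
    val <- rev(val)
    tmp <- left_mean; left_mean <- right_mean; right_mean <- tmp
    reflected <- TRUE
  }
  b_meas <- left_mean
  c_meas <- right_mean
  imax <- which.max(val)
  bmd_max <- val[imax]
  if (bmd_max <= c_meas)
    stop("lat50_measure: degenerate profile (bmd_max <= trabecular level)")

  cross_left <- .crossing_outward(pos, val, imax, (bmd_max + b_meas) / 2, -1L)
  if (is.na(cross_left))
    stop("lat50_measure: no 50% crossing found on the soft-tissue (left) side")
  cross_right <- .crossing_outward(pos, val, imax, (bmd_max + c_meas) / 2, +1L)
  if (is.na(cross_right))
    stop("lat50_measure: no 50% crossing found on the trabecular (right) side")

  bmc50 <- .piecewise_linear_integral(pos, val, cross_left, cross_right)

  structure(
    list(bmd_max = bmd_max, b_meas = b_meas, c_meas = c_meas,
         T = bmd_max / bmd_ref, R = c_meas / bmd_ref, S = b_meas / bmd_ref,
         t_minus = cross_left, t_plus = cross_right,
         bmc50_meas = bmc50, a50 = (cross_right - cross_left) / 2,
         bmd_ref = bmd_ref,
         tail_fraction = tail_fraction, smooth_window = as.integer(smooth_window),
         spacing = profile$spacing, reflected = reflected),
    class = "lat50_measurement"
  )
}

# First crossing of `level` scanning outward from the peak index in direction
# `dir` (-1 left, +1 right); linear interpolation between bracketing samples.
.crossing_outward <- function(pos, val, imax, level, dir) {
  i <- imax
  repeat {
    j <- i + dir
    if (j < 1L || j > length(val)) return(NA_real_)
    if ((val[j] < level) && (val[i] >= level)) {
      # crossing between samples i (>= level) and j (< level)
      frac <- (level - val[i]) / (val[j] - val[i])
      return(pos[i] + frac * (pos[j] - pos[i]))
    }
    i <- j
  }
}

# Trapezoidal integral of the piecewise linear interpolant of (pos, val)
# between arbitrary bounds ta < tb, including fractional end segments.
.piecewise_linear_integral <- function(pos, val, ta, tb) {
  stopifnot(ta < tb, ta >= pos[1], tb <= pos[length(pos)])
  f <- stats::approxfun(pos, val)
  knots <- pos[pos > ta & pos < tb]
  xs <- c(ta, knots, tb)
  ys <- f(xs)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' @export
print.lat50_measurement <- function(x, ...) {
  cat("lat50_measurement: bmd_max =", format(x$bmd_max, digits = 6),
      " (T =", format(x$T, digits = 5), ")\n")
  cat("  backgrounds: b =", format(x$b_meas, digits = 5),
      ", c =", format(x$c_meas, digits = 5),
      " (S =", format(x$S, digits = 4), ", R =", format(x$R, digits = 4), ")\n")
  cat("  50% points: [", format(x$t_minus, digits = 6), ",",
      format(x$t_plus, digits = 6), "] mm; a50 =",
      format(x$a50, digits = 6), "mm; BMC50 =",
      format(x$bmc50_meas, digits = 6), "\n")
  invisible(x)
}

#' Exact LAT50 measurement of an analytic model
#'
#' Computes the measurement record a noiseless, infinitely finely sampled
#' profile would yield, entirely from closed forms: the peak from the
#' peak-offset relation, the 50% points from the normalized crossing
#' equations, and the 50%-interval mass from the closed-form integral.
#' Useful as the exactness oracle for the estimators.
#'
#' @param model a [cortex_model()].
#' @param bmd_ref reference density used for normalization; defaults to the
#'   model's true value.
#' @return a `lat50_measurement`.
#' @export
analytic_measurement <- function(model, bmd_ref = model$bmd_ref) {
  s2 <- sqrt(2) * model$sigma
  abar <- model$a / s2
  B <- model$bmd_ref
  kk <- -0.25 * log((B - model$c) / (B - model$b))
  tmax <- s2 * kk / abar
  bmd_max <- profile_value(model, tmax)
  # true normalized parameters (w.r.t. the model's own density)
  T0 <- bmd_max / B; R0 <- model$c / B; S0 <- model$b / B
  t1 <- s2 * solve_t50(T0, R0, S0, abar, side = "low")
  t2 <- s2 * solve_t50(T0, R0, S0, abar, side = "high")
  structure(
    list(bmd_max = bmd_max, b_meas = model$b, c_meas = model$c,
         T = bmd_max / bmd_ref, R = model$c / bmd_ref, S = model$b / bmd_ref,
         t_minus = t1, t_plus = t2,
         bmc50_meas = profile_auc(model, t1, t2), a50 = (t2 - t1) / 2,
         bmd_ref = bmd_ref,
         tail_fraction = NA_real_, smooth_window = NA_integer_,
         spacing = 0, reflected = FALSE),
    class = "lat50_measurement"
  )
}

#' LAT50 thickness estimate
#'
#' The 50%-threshold thickness `t_plus - t_minus` (= `2 * a50`). Independent
#' of the reference density; accurate for thick cortices but a systematic
#' overestimate once the thickness falls below roughly one PSF FWHM, because
#' mass blurred outside the true cortex is still enclosed by the 50% points.
#'
#' @param m a [lat50_measure()] result.
#' @return a `thickness_estimate` with `method = "LAT50"`.
#' @export
lat50_thickness <- function(m) {
  stopifnot(inherits(m, "lat50_measurement"))
  thickness_estimate(thickness = m$t_plus - m$t_minus, method = "LAT50",
                     K_used = NA_real_, bmc_cort = NA_real_,
                     regularized = FALSE,
                     diagnostics = list(t_minus = m$t_minus, t_plus = m$t_plus))
}

#' Thickness estimate container
#'
#' Method-tagged thickness with diagnostics, shared by all estimators.
#'
#' @param thickness full thickness `2a`, mm.
#' @param method one of "LAT50", "MPA", "DM", "HMPA".
#' @param K_used correction factor applied (NA where not applicable).
#' @param bmc_cort recovered cortical mass (NA where not applicable).
#' @param regularized TRUE when the near-singular clamp `T -> 1 - eps` fired.
#' @param diagnostics free-form named list.
#' @return an object of class `thickness_estimate`.
#' @export
thickness_estimate <- function(thickness, method, K_used = NA_real_,
                               bmc_cort = NA_real_, regularized = FALSE,
                               diagnostics = list()) {
  if (!(thickness > 0)) stop("thickness_estimate: thickness must be > 0")
  structure(
    list(thickness = thickness, half_thickness = thickness / 2,
         method = method, K_used = K_used, bmc_cort = bmc_cort,
         regularized = isTRUE(regularized), diagnostics = diagnostics),
    class = "thickness_estimate"
  )
}

#' @export
print.thickness_estimate <- function(x, ...) {
  cat(sprintf("%s thickness estimate: %.6g mm (a = %.6g mm)\n",
              x$method, x$thickness, x$half_thickness))
  if (is.finite(x$K_used))
    cat("  K =", format(x$K_used, digits = 6),
        "; BMC_cort =", format(x$bmc_cort, digits = 6), "\n")
  if (x$regularized) cat("  [near-singular clamp T -> 1 - eps applied]\n")
  if (!is.null(x$diagnostics$branch))
    cat("  branch:", x$diagnostics$branch, "\n")
  invisible(x)
}
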