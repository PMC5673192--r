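#' Regularize a near-singular measurement
#'
#' The model requires `bmd_max < bmd_ref` (`T < 1`); noise or an
#' underestimated reference density can violate this. Following the
#' preferred correction — decrease the measured maximum rather than inflate
#' the reference — the measurement's `bmd_max` is clamped to
#' `(1 - eps) * bmd_ref` and the copy is flagged `regularized`. Measurements
#' already in the regular domain are returned unchanged (flag unset).
#'
#' @param m a [lat50_measure()] result.
#' @param bmd_ref reference density defining the singular level; defaults to
#'   the one stored in the measurement.
#' @param eps clamp margin, default 1e-6.
#' @return a `lat50_measurement` with an added `regularized` flag.
#' @export
regularize_measurement <- function(m, bmd_ref = m$bmd_ref, eps = 1e-6) {
  stopifnot(inherits(m, "lat50_measurement"), bmd_ref > 0)
  out <- m
  if (m$bmd_max >= bmd_ref) {
    out$bmd_max <- (1 - eps) * bmd_ref
    out$T <- out$bmd_max / m$bmd_ref
    out$regularized <- TRUE
  } else {
    out$regularized <- FALSE
  }
  out
}

#' Hybrid (HMPA) thickness estimate
#'
#' Combines the model-based estimate with the 50%-threshold one: on an ideal
#' noiseless profile the LAT50 thickness never undershoots the truth, so
#' `a_50` is a natural upper bound for the model-based `a_MPA`. Whenever
#' `a_MPA >= a_50` — which happens for thick cortices when the reference
#' density is misspecified, and in the clamped near-singular regime — the
#' LAT50 value is the more trustworthy one. The hybrid therefore returns the
#' smaller of the two half-thicknesses, per profile, with no thickness
#' threshold involved. The MPA branch always runs with the near-singular
#' clamp enabled.
#'
#' @inheritParams mpa_thickness
#' @param margin optional switch margin (experimental): the LAT50 branch is
#'   taken already when `a_MPA >= a_50 - margin`, anticipating an expected
#'   positive error in the measured profile maximum. Default 0 (the plain
#'   upper-bound rule).
#' @return a `thickness_estimate` with `method = "HMPA"`; the diagnostics
#'   name the selected branch.
#' @export
hmpa_thickness <- function(m, bmd_ref, lut = NULL, margin = 0, eps = 1e-6) {
  stopifnot(inherits(m, "lat50_measurement"))
  est50 <- tryCatch(lat50_thickness(m), error = function(e) e)
  estm <- tryCatch(mpa_thickness(m, bmd_ref, lut = lut, regularize = TRUE,
                                 eps = eps),
                   error = function(e) e)
  if (inherits(est50, "error") && inherits(estm, "error"))
    stop("hmpa_thickness: both branches failed (LAT50: ",
         conditionMessage(est50), "; MPA: ", conditionMessage(estm), ")")
  if (inherits(estm, "error")) {
    sel <- est50; branch <- "LAT50"; other <- NA_real_
    regularized <- FALSE; K_used <- NA_real_; bmc <- NA_real_
  } else if (inherits(est50, "error")) {
    sel <- estm; branch <- "MPA"; other <- NA_real_
    regularized <- estm$regularized; K_used <- estm$K_used; bmc <- estm$bmc_cort
  } else if (estm$half_thickness >= est50$half_thickness - margin) {
    sel <- est50; branch <- "LAT50"; other <- estm$half_thickness
    regularized <- estm$regularized; K_used <- NA_real_; bmc <- NA_real_
  } else {
    sel <- estm; branch <- "MPA"; other <- est50$half_thickness
    regularized <- estm$regularized; K_used <- estm$K_used; bmc <- estm$bmc_cort
  }
  thickness_estimate(
    thickness = sel$thickness, method = "HMPA", K_used = K_used,
    bmc_cort = bmc, regularized = regularized,
    diagnostics = list(branch = branch, a_other = other, margin = margin)
  )
}
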