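# Simulation studies: seeded batch sweeps of estimator accuracy, producing
# tidy result tables. Relative error is (2*a_hat - 2*a) / (2*a) * 100 and the
# thickness axis is also reported normalized by the PSF FWHM.

# deterministic per-replicate seed derived from a master seed (kept < 2^31)
.derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 7919 + counter * 104729) %% 2147483647) + 1L
}

.default_study_model <- function(a, sigma = 1.5, bmd_ref = 800, c = 150, b = 0)
  cortex_model(a = a, sigma = sigma, bmd_ref = bmd_ref, b = b, c = c)

#' Noise accuracy study
#'
#' Monte-Carlo sweep of estimator accuracy under additive Gaussian profile
#' noise, on the standard simulation settings (reference density 800, PSF
#' sigma 1.5 mm, trabecular 150, soft tissue 0, true reference used) over
#' half-thicknesses from 0.5 to 7 sigma, with noise levels 30 and 37 density
#' units and 250 replicates per cell by default. Reduced replicate counts
#' are supported for quick runs.
#'
#' @param a_grid half-thickness grid, mm; default 28 points over
#'   `[0.5, 7] * sigma`.
#' @param noise_levels noise standard deviations.
#' @param n_reps replicates per (thickness, noise) cell.
#' @param methods subset of `"lat50"`, `"mpa"`, `"dm"`.
#' @param sigma,bmd_ref,c,b model parameters.
#' @param spacing profile sampling step; default FWHM/20.
#' @param seed master seed; every row records its derived seed.
#' @return a data.frame with columns `a_true`, `two_a_over_fwhm`, `method`,
#'   `noise_sd`, `replicate`, `est_thickness`, `relative_error_pct`, `seed`.
#' @export
run_noise_study <- function(a_grid = seq(0.5, 7, length.out = 28) * sigma,
                            noise_levels = c(30, 37), n_reps = 250L,
                            methods = c("lat50", "mpa"),
                            sigma = 1.5, bmd_ref = 800, c = 150, b = 0,
                            spacing = NULL, seed = 1L) {
  methods <- match.arg(methods, c("lat50", "mpa", "dm"), several.ok = TRUE)
  rows <- vector("list", 0L)
  counter <- 0L
  for (a in a_grid) {
    model <- .default_study_model(a, sigma, bmd_ref, c, b)
    sp <- if (is.null(spacing)) fwhm(model) / 20 else spacing
    for (ns in noise_levels) {
      for (rep_i in seq_len(n_reps)) {
        counter <- counter + 1L
        sd_i <- .derive_seed(seed, counter)
        pr <- simulate_profile(model, spacing = sp, noise_sd = ns, seed = sd_i)
        m <- tryCatch(lat50_measure(pr, bmd_ref), error = function(e) NULL)
        for (meth in methods) {
          est <- tryCatch(switch(
            meth,
            lat50 = if (!is.null(m)) lat50_thickness(m),
            mpa = if (!is.null(m)) mpa_thickness(m, bmd_ref, regularize = TRUE),
            dm = dm_thickness(pr, bmd_ref = bmd_ref, seed = sd_i)
          ), error = function(e) NULL)
          th <- if (is.null(est)) NA_real_ else est$thickness
          rows[[length(rows) + 1L]] <- data.frame(
            a_true = a, two_a_over_fwhm = 2 * a / fwhm(model),
            method = toupper(meth), noise_sd = ns, replicate = rep_i,
            est_thickness = th,
            relative_error_pct = 100 * (th - 2 * a) / (2 * a),
            seed = sd_i)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Reference-density error study
#'
#' Deterministic (noiseless) error curves of the estimators when the assumed
#' reference density is off by the given relative amounts. No noise is added
#' so that the pure effect of the misspecification — and of the hybrid's
#' upper bound — is visible. Profiles are sampled densely (FWHM/50).
#'
#' @param a_grid half-thickness grid, mm.
#' @param error_levels relative errors in the reference density (e.g. -0.10).
#' @param methods subset of `"lat50"`, `"mpa"`, `"hmpa"`, `"dm"`.
#' @inheritParams run_noise_study
#' @return a data.frame with columns `a_true`, `two_a_over_fwhm`, `method`,
#'   `bmd_ref_error_pct`, `est_thickness`, `relative_error_pct`,
#'   `regularized`, `branch`.
#' @export
run_bmdref_error_study <- function(a_grid = seq(0.5, 7, length.out = 28) * sigma,
                                   error_levels = c(-0.10, -0.05, 0, 0.05, 0.10),
                                   methods = c("lat50", "mpa", "hmpa"),
                                   sigma = 1.5, bmd_ref = 800, c = 150, b = 0,
                                   spacing = NULL, seed = 1L) {
  methods <- match.arg(methods, c("lat50", "mpa", "hmpa", "dm"),
                       several.ok = TRUE)
  rows <- vector("list", 0L)
  for (a in a_grid) {
    model <- .default_study_model(a, sigma, bmd_ref, c, b)
    sp <- if (is.null(spacing)) fwhm(model) / 50 else spacing
    pr <- simulate_profile(model, spacing = sp, noise_sd = 0)
    m <- lat50_measure(pr, bmd_ref)
    for (err in error_levels) {
      B <- bmd_ref * (1 + err)
      for (meth in methods) {
        est <- tryCatch(switch(
          meth,
          lat50 = lat50_thickness(m),
          mpa = mpa_thickness(m, B, regularize = TRUE),
          hmpa = hmpa_thickness(m, B),
          dm = dm_thickness(pr, bmd_ref = B, seed = seed)
        ), error = function(e) NULL)
        th <- if (is.null(est)) NA_real_ else est$thickness
        rows[[length(rows) + 1L]] <- data.frame(
          a_true = a, two_a_over_fwhm = 2 * a / fwhm(model),
          method = toupper(meth), bmd_ref_error_pct = 100 * err,
          est_thickness = th,
          relative_error_pct = 100 * (th - 2 * a) / (2 * a),
          regularized = if (is.null(est)) NA else est$regularized,
          branch = if (!is.null(est) && !is.null(est$diagnostics$branch))
            est$diagnostics$branch else NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Taylor sensitivity validation study
#'
#' For each requested normalized half-thickness, compares the Taylor
#' error prediction (linear, and with the second-order `T` term) against the
#' ground-truth error recomputed by the full solver, over a range of
#' perturbations in one parameter at a time. Default operating point:
#' reference density 1000, `R = 1/3`, `sigma = 1`, soft tissue 0.
#'
#' @param abar_points normalized half-thickness values `a / (sqrt(2) sigma)`.
#' @param vary which parameters to perturb: subset of `"T"`, `"R"`,
#'   `"BMDref"`.
#' @param rel_range maximal relative perturbation (fraction of the
#'   parameter's base value); the sweep uses `n_steps` symmetric steps.
#' @param n_steps perturbation steps per side.
#' @param bmd_ref,R,sigma operating point.
#' @return a data.frame with columns `abar`, `param`, `delta` (perturbation,
#'   in the parameter's units), `true_delta_a`, `taylor_linear`,
#'   `taylor_quadratic` (linear + T^2 term; equals linear for non-T
#'   parameters).
#' @export
run_sensitivity_study <- function(abar_points = c(0.5, 1.25, 1.64, 3.5),
                                  vary = c("T", "R", "BMDref"),
                                  rel_range = 0.05, n_steps = 8L,
                                  bmd_ref = 1000, R = 1 / 3, sigma = 1) {
  vary <- match.arg(vary, several.ok = TRUE)
  rows <- vector("list", 0L)
  for (ab in abar_points) {
    model <- cortex_model(a = ab * sqrt(2) * sigma, sigma = sigma,
                          bmd_ref = bmd_ref, b = 0, c = R * bmd_ref)
    m <- analytic_measurement(model)
    base <- list(T = m$bmd_max / bmd_ref, R = R, B = bmd_ref)
    for (param in vary) {
      base_val <- switch(param, T = base$T, R = base$R, BMDref = base$B)
      deltas <- seq(-rel_range, rel_range, length.out = 2L * n_steps + 1L) *
        base_val
      for (d in deltas) {
        args <- list(d_T = 0, d_R = 0, d_bmdref = 0)
        if (param == "T") args$d_T <- d
        if (param == "R") args$d_R <- d
        if (param == "BMDref") args$d_bmdref <- d
        true_d <- tryCatch(
          sensitivity_fd(m, bmd_ref, d_T = args$d_T, d_R = args$d_R,
                         d_bmdref = args$d_bmdref),
          error = function(e) NA_real_)
        rep_full <- tryCatch(
          taylor_delta_a(m, bmd_ref, d_T = args$d_T, d_R = args$d_R,
                         d_bmdref = args$d_bmdref),
          error = function(e) NULL)
        if (is.null(rep_full)) {
          lin <- quadr <- NA_real_
        } else {
          quadr <- rep_full$predicted_delta_a
          lin <- quadr - 0.5 * rep_full$d2_a_dT2 * args$d_T^2
        }
        rows[[length(rows) + 1L]] <- data.frame(
          abar = ab, param = param, delta = d, true_delta_a = true_d,
          taylor_linear = lin, taylor_quadratic = quadr)
      }
    }
  }
  do.call(rbind, rows)
}
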