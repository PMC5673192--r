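#' Ground-truth cortex model
#'
#' Describes the 1D "box cortex" imaged through a Gaussian point spread
#' function: a slab of compact cortical bone of half-thickness `a` and
#' density `bmd_ref` centred at the origin, with soft tissue of density `b`
#' on the left and trabecular bone of density `c` on the right. The imaged
#' profile is the convolution of these three box functions with a Gaussian
#' of standard deviation `sigma`.
#'
#' The canonical orientation puts the denser background (trabecular bone) on
#' the right, i.e. `c >= b`. If a model is supplied with `b > c` it is
#' reflected (`t -> -t`), which leaves the profile geometry unchanged, and
#' the `reflected` flag is set.
#'
#' Density units (line density mg/mm, volumetric mg/cm3, or HU) are carried
#' as opaque metadata: every estimator here is invariant under a common
#' rescaling of the profile and the reference density.
#'
#' @param a half-thickness of the cortex, mm (`> 0`).
#' @param sigma Gaussian PSF standard deviation, mm (`> 0`).
#' @param bmd_ref density of compact cortical bone (must exceed `b` and `c`).
#' @param b soft-tissue background density (`>= 0`).
#' @param c trabecular background density (`>= 0`).
#' @param units free-form unit label, metadata only.
#' @return an object of class `cortex_model`.
#' @seealso [profile_value()], [profile_auc()], [simulate_profile()]
#' @examples
#' m <- cortex_model(a = 0.75, sigma = 1.5, bmd_ref = 800, b = 0, c = 150)
#' fwhm(m)
#' @export
cortex_model <- function(a, sigma, bmd_ref, b = 0, c = 0, units = "density") {
  stopifnot(is.numeric(a), is.numeric(sigma), is.numeric(bmd_ref),
            length(a) == 1L, length(sigma) == 1L, length(bmd_ref) == 1L)
  if (!(a > 0)) stop("cortex_model: half-thickness `a` must be > 0")
  if (!(sigma > 0)) stop("cortex_model: `sigma` must be > 0")
  if (b < 0 || c < 0) stop("cortex_model: background densities must be >= 0")
  if (!(bmd_ref > b && bmd_ref > c))
    stop("cortex_model: `bmd_ref` must exceed both background densities")
  reflected <- FALSE
  if (b > c) {   # enforce canonical orientation: trabecular (denser) right
    tmp <- b; b <- c; c <- tmp
    reflected <- TRUE
  }
  structure(
    list(a = a, sigma = sigma, bmd_ref = bmd_ref, b = b, c = c,
         units = units, reflected = reflected),
    class = "cortex_model"
  )
}

#' @rdname cortex_model
#' @param model a `cortex_model`.
#' @export
fwhm <- function(model) 2 * sqrt(2 * log(2)) * model$sigma

#' @export
print.cortex_model <- function(x, ...) {
  cat("cortex_model: a =", x$a, "mm, sigma =", x$sigma,
      "mm (FWHM", format(fwhm(x), digits = 4), "mm)\n")
  cat("  densities [", x$units, "]: cortex", x$bmd_ref,
      ", trabecular", x$c, ", soft tissue", x$b, "\n")
  if (x$reflected) cat("  (input was reflected to canonical orientation)\n")
  invisible(x)
}

#' Closed-form blurred profile value
#'
#' Evaluates the three-erf expression for the convolution of the box cortex
#' with the Gaussian PSF,
#' \deqn{P(t) = \frac{B}{2}\left[\mathrm{erf}\frac{t+a}{\sqrt2\sigma}
#'   - \mathrm{erf}\frac{t-a}{\sqrt2\sigma}\right]
#'   + \frac{c}{2}\left[1+\mathrm{erf}\frac{t-a}{\sqrt2\sigma}\right]
#'   + \frac{b}{2}\left[1-\mathrm{erf}\frac{t+a}{\sqrt2\sigma}\right],}
#' with \eqn{B} the reference density. Smooth and defined for all real `t`;
#' tends to `b` as \eqn{t\to-\infty} and to `c` as \eqn{t\to+\infty}.
#'
#' @param model a [cortex_model()].
#' @param t position(s) along the profile, mm.
#' @return density value(s), same length as `t`.
#' @export
profile_value <- function(model, t) {
  s2 <- sqrt(2) * model$sigma
  ep <- erf((t + model$a) / s2)
  em <- erf((t - model$a) / s2)
  model$bmd_ref / 2 * (ep - em) + model$c / 2 * (1 + em) + model$b / 2 * (1 - ep)
}

#' Closed-form area under the blurred profile
#'
#' Mass (density x length) of the profile between `t1` and `t2`, via the
#' primitive [er()]. Additive over adjacent intervals; over a wide symmetric
#' interval with zero backgrounds it converges to the true cortical mass
#' `2 * a * bmd_ref`, which blurring preserves.
#'
#' @inheritParams profile_value
#' @param t1,t2 interval bounds, mm, `t1 < t2` (vectors are recycled).
#' @return mass value(s).
#' @export
profile_auc <- function(model, t1, t2) {
  if (any(t1 > t2)) stop("profile_auc: requires t1 <= t2")
  s2 <- sqrt(2) * model$sigma
  ab <- model$a / s2
  z1 <- t1 / s2
  z2 <- t2 / s2
  pref <- model$sigma / sqrt(2)
  model$bmd_ref * pref *
    (er(z2 + ab) - er(z1 + ab) - er(z2 - ab) + er(ab - z1)) +
    model$c * pref * ((z2 - z1) + er(z2 - ab) - er(ab - z1)) +
    model$b * pref * ((z2 - z1) - er(z2 + ab) + er(z1 + ab))
}

#' Sampled 1D profile
#'
#' A discrete profile measurement: strictly increasing, uniformly spaced
#' positions (mm) with density values. At least 16 samples are required and
#' the spacing must be constant to within a relative 1e-9.
#'
#' @param positions numeric vector of positions, mm.
#' @param values numeric vector of densities, same length.
#' @param noise_sd,seed optional provenance metadata for simulated profiles.
#' @param short_tails flag set by [simulate_profile()] when the grid is too
#'   short for reliable tail (background) estimation.
#' @return an object of class `sampled_profile` with elements `positions`,
#'   `values`, `spacing`.
#' @export
sampled_profile <- function(positions, values, noise_sd = NA_real_,
                            seed = NA_integer_, short_tails = FALSE) {
  if (length(positions) != length(values))
    stop("sampled_profile: positions and values differ in length")
  if (length(positions) < 16L)
    stop("sampled_profile: need at least 16 samples")
  d <- diff(positions)
  if (any(d <= 0)) stop("sampled_profile: positions must be strictly increasing")
  spacing <- stats::median(d)
  if (max(abs(d - spacing)) > 1e-9 * max(spacing, 1))
    stop("sampled_profile: spacing not uniform (tolerance 1e-9)")
  structure(
    list(positions = as.numeric(positions), values = as.numeric(values),
         spacing = spacing, noise_sd = noise_sd, seed = seed,
         short_tails = isTRUE(short_tails)),
    class = "sampled_profile"
  )
}

#' @export
print.sampled_profile <- function(x, ...) {
  cat("sampled_profile:", length(x$positions), "samples, spacing",
      format(x$spacing, digits = 6), "mm, range [",
      format(min(x$positions), digits = 6), ",",
      format(max(x$positions), digits = 6), "] mm\n")
  if (x$short_tails) cat("  warning: tails too short for background estimation\n")
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so simulation helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Simulate a noisy sampled profile
#'
#' Samples the analytic blurred profile on a uniform grid centred at 0 and
#' adds i.i.d. zero-mean Gaussian noise. Identical seeds give bitwise
#' identical profiles; the caller's RNG state is left untouched.
#'
#' @inheritParams profile_value
#' @param spacing sample spacing, mm; default FWHM/20 (the sampling step is
#'   not prescribed by the model, see the methods vignette).
#' @param half_length half extent of the grid, mm; should be at least
#'   `a + 4 * FWHM` so both background tails are well represented. Shorter
#'   grids are simulated but flagged `short_tails`.
#' @param noise_sd standard deviation of the additive Gaussian noise, in the
#'   profile's density units.
#' @param seed integer seed for the noise; `NA` uses the current RNG stream.
#' @return a [sampled_profile()].
#' @export
simulate_profile <- function(model, spacing = fwhm(model) / 20,
                             half_length = model$a + 4 * fwhm(model),
                             noise_sd = 0, seed = NA_integer_) {
  stopifnot(spacing > 0, half_length > 0, noise_sd >= 0)
  n <- floor(half_length / spacing)
  if (2L * n + 1L < 16L)
    stop("simulate_profile: grid would have fewer than 16 samples")
  short <- half_length < model$a + 4 * fwhm(model) - 1e-12
  if (short)
    warning("simulate_profile: grid shorter than a + 4*FWHM; tails flagged")
  pos <- (-n:n) * spacing
  val <- profile_value(model, pos)
  if (noise_sd > 0)
    val <- val + with_seed(seed, stats::rnorm(length(pos), 0, noise_sd))
  sampled_profile(pos, val, noise_sd = noise_sd, seed = seed,
                  short_tails = short)
}
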