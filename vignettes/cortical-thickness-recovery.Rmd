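---
title: "Model-based recovery of cortical bone thickness from blurred CT profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based recovery of cortical bone thickness from blurred CT profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortiprof)
```

## The problem

Clinical quantitative CT cannot resolve a cortical shell much thinner than
the scanner point spread function (PSF): the apparent cortex is blurred,
its peak density drops below the true tissue density, and threshold-based
segmentation overestimates the thickness — by more than 100% for
sub-millimetre cortices at typical in-plane resolutions. `cortiprof`
implements an analytic, optimization-free estimator of the true thickness
from 1D density profiles laid across the cortex, together with the two
standard comparators (the local adaptive 50% threshold, LAT50, and a
whole-profile deconvolution fit, DM), an error-propagation analysis, and
the simulation and phantom machinery to validate all of them.

## The forward model

A profile across the cortex is modelled as three box functions — soft
tissue of density $b$ on the left, cortical bone of density
$\mathrm{BMD}_{ref}$ between $-a$ and $a$, trabecular bone of density $c$
on the right ($c \ge b$ by canonical orientation) — convolved with a
Gaussian PSF of standard deviation $\sigma$:

$$P(t) = \tfrac{B}{2}\!\left[\operatorname{erf}\tfrac{t+a}{\sqrt2\sigma} -
\operatorname{erf}\tfrac{t-a}{\sqrt2\sigma}\right] +
\tfrac{c}{2}\!\left[1+\operatorname{erf}\tfrac{t-a}{\sqrt2\sigma}\right] +
\tfrac{b}{2}\!\left[1-\operatorname{erf}\tfrac{t+a}{\sqrt2\sigma}\right].$$

Closed forms for the area under any stretch of this curve follow from the
primitive $Er(t) = t\operatorname{erf}(t) + e^{-t^2}/\sqrt\pi$, implemented
exactly (`er()`), never by numeric integration. Blurring preserves the
cortical mass $2a B$, which is the physical fact the whole method rests on.

### Normalization convention

All dimensionless ("overline") quantities are positions divided by
$\sqrt2\,\sigma$, so that the erf arguments become $\bar t \pm \bar a$ with
$\bar a = a/(\sqrt2\sigma)$. This is forced by the erf arguments of the
profile formula; the package's round-trip exactness tests (solve the
normalized equations from analytically generated inputs and compare
$\bar a$ with $a/(\sqrt2\sigma)$) pin the convention down empirically.
Note that $\sigma$ itself never enters the estimator — it cancels in the
thickness formula — which is the method's key practical advantage over
deconvolution fits.

## The estimators

**LAT50.** Each edge is located where the profile crosses halfway between
its maximum and the adjacent background level; thickness is the distance
between the two crossings. Independent of $\mathrm{BMD}_{ref}$; on an
ideal noiseless profile it never undershoots, and it overestimates
strongly once $2a$ falls below about one FWHM.

**MPA.** The measured parameters $T = \mathrm{BMD}_{max}/B$, $R = c/B$,
$S = b/B$ determine the normalized solution: $\bar a$ as the unique root
of the peak equation, the two normalized 50% points, and the correction
factor $K(T,R,S) = \mathrm{BMC}_{50\%}/\mathrm{BMC}_{cort}$. The measured
50%-interval mass is then converted to thickness,
$a = \mathrm{BMC}_{50\%,meas} / (2 B K)$. Exact on its own model; the unit
root is guaranteed because the peak-equation residual is strictly
increasing in $\bar a$.

**HMPA.** Because the ideal LAT50 thickness is an upper bound for the
truth, the hybrid takes the smaller of the MPA and LAT50 half-thicknesses,
per profile, with no thickness-threshold heuristic. This caps the error
caused by a misspecified reference density from above by the LAT50 error
curve (a *signed* bound: with an overestimated reference the hybrid can
undershoot in the midrange, below the LAT50 curve — the bound is on the
curve, not on the absolute error). An optional `margin` argument shifts
the switch point to anticipate an expected positive error in the measured
maximum; it defaults to 0 and is documented as experimental.

**DM.** Bounded multi-start least squares of the full profile model with
free $(a, t_0, \sigma, c, b)$ and fixed $B$. This is a faithful stand-in
for published deconvolution fits whose exact objective is not public; it
is implemented with L-BFGS-B and the analytic model gradient because
`nls()` cannot handle the zero-residual noiseless case that the exactness
claim requires.

## Numerical choices

* **Root solving.** $\bar a$ is bracketed by $[10^{-8}, 1]$ with geometric
  expansion (×2) until a sign change, then solved by Brent's method and
  polished by bisection to a residual below $10^{-12}$. The 50% points are
  bracketed outward from the peak $\bar t_{max} = k/\bar a$ in steps of
  $\max(\bar a, 1)$, failing after $50(\bar a + 1)$.
* **Singular clamp.** Noise or an underestimated reference can push
  $\mathrm{BMD}_{max} \ge B$ ($T \ge 1$), outside the model's domain. The
  preferred correction decreases the measured maximum: $T$ is clamped to
  $1 - 10^{-6}$, the estimate is flagged `regularized`, and the hybrid
  always runs with the clamp enabled. Without `regularize = TRUE`, MPA
  raises an error of class `cortiprof_singular`.
* **Guard band for sensitivity.** Within $1 - T < 10^{-3}$ the Taylor
  machinery is analytically valid but practically useless (the solution
  degenerates as $T \to 1$); `k_derivatives()` refuses there and points to
  `lat50_sensitivity()`. The guard can be lowered explicitly, which is how
  the test suite demonstrates the genuine divergence of the expansion at
  $\bar a = 3.5$.
* **Lookup table.** $K$ depends only on $(T, R)$ once $S = 0$ is assumed,
  so it is precomputed on a grid (default $T \in [0.02, 0.999]$ step
  0.002, $R \in [0, 0.9]$ step 0.01) and interpolated bilinearly; the
  default step was chosen so the interpolation error in $K$ stays below
  $10^{-3}$ (verified by test). Queries outside the hull or in cells
  touching the infeasible region $T \le R$ fall back to the direct solver
  with a warning; profiles with $S \neq 0$ bypass the table. The table is
  persisted as JSON rather than a binary container so that the artifact is
  plain text.
* **Thick-cortex limits in double precision.** $T$ is not representable
  below 1 past $\bar a \approx 5.8$, so claims "in the limit" are tested
  either at representable operating points or directly on the analytic
  profile. In the $R = S = 0$ thick limit the correction factor obeys
  $1 - K = 1/(2\sqrt{\pi}\,\bar a)$ — each edge blurs $\sigma/\sqrt{2\pi}$
  of mass outside the 50% interval — which the tests assert in place of
  the naive expectation $K \approx 1$.

## Sensitivity analysis

Errors in the measured mass, $T$, $R$, and the reference density propagate
to the half-thickness through a Taylor expansion whose coefficients come
from implicit differentiation of the peak and crossing equations (first
order in everything, second order in $T$ only; mixed second-order terms
are deliberately omitted, and the non-monotone dependence of the right 50%
point on $T$ is why the $T^2$ term is kept). All derivatives, including
$\partial^2 K/\partial T^2$ via full second-order implicit
differentiation, are validated against Richardson central differences of
the direct solver, and the whole prediction against ground-truth
recomputation (`sensitivity_fd()`). The reference-density derivative
combines the explicit $1/B$ factor with the chained shift of $T$ and $R$.

## What the synthetic data emulates

`simulate_profile()` reproduces the validation study conditions: reference
density 800, $\sigma = 1.5$ mm, trabecular 150, soft tissue 0, additive
i.i.d. Gaussian noise of 30 or 37 density units (matching reported
calibration-phantom noise at typical clinical exposures), half-thickness
sweeps from $0.5\sigma$ to $7\sigma$, 250 replicates per cell. The
sampling step is not prescribed by the study and defaults to FWHM/20;
error-curve (noiseless) studies sample at FWHM/50. Per-replicate seeds are
derived from the master seed by a counter scheme, so every table row is
reproducible in isolation.

The 2D annulus phantom stands in for an anthropomorphic forearm phantom
cross-section: a ring of cortex density 800 (inner trabecular 150, outer
soft tissue 0) at 0.2 mm pixels, isotropic Gaussian blur of 1 mm and pixel
noise of about 20 — numbers chosen to sit in the clinically relevant
partial-volume regime for the 0.5–3 mm shell thicknesses studied.
Boundary pixels are antialiased by 16×16 supersampling (interior pixels
classified exactly), which keeps the rasterized ring mass within a few
$10^{-5}$ of the analytic area; exact circular-segment coverage was judged
not worth the complexity. Profiles are sampled bilinearly along inward
radial normals; the segmentation-based thickness takes, at each outer
(periosteal) point, the shortest distance to the polygonal inner contour,
which can never exceed the per-ray thickness and is mildly biased low.
Model-based edge points are centred on the 50%-crossing midpoint of each
ray.

What a green test does **not** establish: the generator has no real
scanner PSF (no reconstruction-kernel shape, no through-plane blur), no
correlated noise, no cortical porosity or locally varying reference
density, and no segmentation errors in the periosteal normal direction
beyond the deliberate tilt experiments. Real-scanner accuracy therefore
cannot be inferred from these tests; they establish internal correctness
of the estimators on their stated model.

## Design decisions that were genuinely open

* **Background windows.** The source method never defines how the
  trabecular and soft-tissue compartment densities are averaged; the
  measurement uses the outermost 20% of samples on each side by default,
  exposed as `tail_fraction` and recorded in the measurement for
  provenance.
* **Multiple crossings under noise.** The crossing nearest the peak is
  taken on each side — conservative against detached noise blobs.
* **Smoothing.** Off by default; an optional centred running mean is
  provided, with the documented caveat that it lowers the measured
  maximum and so biases $T$ down.
* **DM initialization.** Centre and half-thickness from the LAT50
  measurement, PSF width from the 10–90% rise of the leading edge, plus
  five seeded multiplicative jitter restarts — the referenced fits publish
  no initialization and warn about local minima.
* **Alternative parameter sets.** Using a measured 50%-point coordinate
  instead of the interval mass would also determine $\sigma$ and $a$, but
  a single coordinate is less stable than an integral under local profile
  variation; this route is documented, not implemented.

## Worked example

```{r example}
model <- cortex_model(a = 0.75, sigma = 1.5, bmd_ref = 800, b = 0, c = 150)
profile <- simulate_profile(model, noise_sd = 30, seed = 42)
meas <- lat50_measure(profile, bmd_ref = 800)
lat50_thickness(meas)
mpa_thickness(meas, bmd_ref = 800, regularize = TRUE)
hmpa_thickness(meas, bmd_ref = 800)
```

## Known limitations

* Non-Gaussian PSFs (sharp reconstruction kernels resemble a sinc) are out
  of scope; everything is Gaussian.
* The reference density must be supplied; estimating it from data is
  explicitly not addressed, only the sensitivity to its error.
* The phantom is 2D; 3D femur segmentation and real CT ingestion are
  non-goals.
* Profile smoothing effects on the measured parameters are not propagated
  into the error model.
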