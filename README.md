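# cortiprof

Cortical bone thickness recovery from partial-volume-blurred CT intensity
profiles.

## The problem

Clinical quantitative CT images the cortical shell of bones (femoral neck,
vertebrae, forearm) at a resolution comparable to, or coarser than, the
shell itself. The scanner point spread function (PSF) blurs the cortex:
its apparent peak density drops below the true tissue density and
threshold-based edge detection — including the standard local adaptive 50%
method (LAT50) — overestimates the thickness, by over 100% for
sub-millimetre cortices. Deconvolution fits recover the thickness but
require a nonlinear optimization, knowledge of the PSF width, and an
assumed cortical reference density.

`cortiprof` implements an analytic alternative. Along a 1D profile across
the cortex, model the true structure as three boxes (soft tissue `b` |
cortex `BMD_ref` on `[-a, a]` | trabecular bone `c`) convolved with a
Gaussian PSF of width σ:

    P(t) = B/2 [erf((t+a)/(√2σ)) − erf((t−a)/(√2σ))]
         + c/2 [1 + erf((t−a)/(√2σ))] + b/2 [1 − erf((t+a)/(√2σ))]

From three measured numbers — the normalized profile maximum
`T = BMD_max/BMD_ref` and backgrounds `R = c/BMD_ref`, `S = b/BMD_ref` —
a single monotone scalar equation yields the normalized half-thickness
`ā = a/(√2σ)`, the two 50%-threshold points, and the mass correction
factor `K(T,R,S) = BMC_50%/BMC_cort`. The thickness follows from the
measured 50%-interval mass alone:

    2a = BMC_50%,meas / (BMD_ref · K)

No optimization, a unique solution, and — because K is dimensionless —
no PSF width anywhere in the estimator (MPA, model-based profile
analysis). Since the ideal LAT50 thickness never undershoots, the hybrid
estimator (HMPA) takes the smaller of the MPA and LAT50 values per
profile, which caps the error from a misspecified reference density by
the LAT50 error curve. A two-entry lookup table for `K(T, R)` makes the
whole thing a table lookup at run time.

The package also provides the deconvolution baseline (DM, whole-profile
least squares), a Taylor error-propagation analysis with a ground-truth
recomputation oracle, a synthetic 2D annulus phantom with radial profile
extraction and segmentation-based (voxel-to-surface) thickness, and
seeded batch studies of accuracy under noise and reference-density error.

## Worked example

A thin cortex (true thickness 1.5 mm, σ = 1.5 mm ⇒ 2a/FWHM ≈ 0.42) with
realistic noise:

```r
library(cortiprof)
model   <- cortex_model(a = 0.75, sigma = 1.5, bmd_ref = 800, b = 0, c = 150)
profile <- simulate_profile(model, noise_sd = 30, seed = 42)
meas    <- lat50_measure(profile, bmd_ref = 800)

lat50_thickness(meas)
#> LAT50 thickness estimate: 3.37131 mm (a = 1.68565 mm)
mpa_thickness(meas, bmd_ref = 800, regularize = TRUE)
#> MPA thickness estimate: 1.45151 mm (a = 0.725756 mm)
#>   K = 0.916117 ; BMC_cort = 1161.21
hmpa_thickness(meas, bmd_ref = 800)
#> HMPA thickness estimate: 1.45151 mm (a = 0.725756 mm)
#>   K = 0.916117 ; BMC_cort = 1161.21
#>   branch: MPA
dm_thickness(profile, bmd_ref = 800, seed = 1)
#> DM thickness estimate: 1.56982 mm (a = 0.784911 mm)
```

The 50% threshold reads 3.37 mm off a 1.5 mm cortex (+125%); the
model-based estimate recovers 1.45 mm (−3%) by correcting the measured
50%-interval mass (1064) with K = 0.916 instead of trusting the blurred
geometry. On noiseless profiles MPA and DM are exact to numerical
precision.

Command line (same machinery):

```sh
inst/cli/cortiprof simulate --a 0.75 --sigma 1.5 --bmd-ref 800 --c 150 \
    --noise-sd 30 --seed 42 --out profile.txt
inst/cli/cortiprof estimate --method hmpa --bmd-ref 800 profile.txt
```

## Layout

- `R/` — forward model, LAT50 measurement, MPA solver + lookup table,
  hybrid, DM fit, sensitivity analysis, annulus phantom, batch studies,
  file formats and CLI.
- `tests/testthat/` — unit, property and oracle tests per module;
  `test-acceptance.R` holds the acceptance criteria.
- `vignettes/cortical-thickness-recovery.Rmd` — the methods vignette:
  model, assumptions, numerical choices, what the synthetic data does and
  does not emulate.
- `scripts/acceptance.R` — the acceptance report generator.
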