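# oximap

Tissue oxygenation and perfusion mapping from snapshot-mosaic
multispectral images of the exposed heart, with a pre- versus
post-bypass statistical comparison. The package is written for
researchers in biomedical optics and surgical imaging who want a
tested, reproducible implementation of the full chain from raw mosaic
sensor frames to a patency-oriented report — plus a phantom simulator
that stands in for clinical recordings, which are typically not
shareable.

## What it computes

A snapshot mosaic camera (a 16-band visible camera with a 4×4 filter
tile, 460–600 nm, and a 25-band near-infrared camera with a 5×5 tile,
660–950 nm) records one band per pixel in a single exposure. The
pipeline:

1. **Radiometric calibration** — dark subtraction, Lanczos demosaicing
   onto the common pixel grid, bilateral denoising per band,
   manufacturer spectral correction, white balancing against a 95%
   reflectance reference, and per-pixel L1 normalization of the
   reflectance spectrum (removing the camera-to-heart distance scale).
2. **Beer–Lambert spectral unmixing** — per pixel, absorbance
   a(w) = −log r(w) is fit by unconstrained linear least squares as

       a(w) = μₐ,HbO₂(w)·c_HbO₂ + μₐ,Hb(w)·c_Hb + G

   giving tissue **oxygenation** c_HbO₂/(c_HbO₂+c_Hb), **relative
   hemoglobin content** c_HbO₂+c_Hb (a.u., up to the unknown path
   length), and the fit quality **COD** (R²).
3. **Perfusion indices** — ratios of mean L1-normalized absorbance:
   530–580 nm / 496–504 nm on the visible camera (superficial
   perfusion) and 826–928 nm / 668–739 nm on the NIR camera (deep
   perfusion). A synthetic RGB image (596/550/460 nm bands, histogram
   equalized) supports vessel segmentation.
4. **ROI statistics** — pixels with COD < 0.7 are excluded (specular
   reflections, hemoglobin-poor areas), the segmented-vessel ROI is
   aggregated, and pre/post differences are tested with a
   random-intercept linear mixed model (phase as fixed effect, patient
   as random effect, REML via lme4), significance at p < 0.01, with a
   patient-level paired t-test reported alongside.
5. **Phantom simulator** — ground-truth scenes (curved vessel, smooth
   heterogeneous background, optional specular highlights) rendered
   into raw mosaic frames with realistic shot/read noise, so every
   stage is testable end to end against known truth.

See `vignettes/oxygenation-mapping.Rmd` for the models, defaults and
design decisions.

## Worked example

```r
library(oximap)

res <- run_pipeline(list(
  seed = 11,
  simulate = list(n_cabg = 2, n_control = 2, height = 96, width = 96)
))
res$report
```

```
   group   parameter   units mean_change sd_change     beta1  p_value significant
    cabg oxygenation percent    1.20e+01  9.69e-02  1.20e+01 0.00e+00        TRUE
    cabg      hb_rel    a.u.   -3.95e-06  4.72e-06 -3.95e-06 8.13e-01       FALSE
    cabg         cod    a.u.    1.20e-04  4.00e-05  1.20e-04 4.80e-01       FALSE
    cabg superficial    a.u.   -5.82e-03  5.43e-04 -5.82e-03 1.31e-09        TRUE
 control oxygenation percent    1.35e-01  9.79e-02  1.35e-01 1.42e-01       FALSE
 control      hb_rel    a.u.    1.23e-05  1.99e-08  1.23e-05 5.57e-01       FALSE
 control         cod    a.u.   -1.35e-04  1.61e-04 -1.35e-04 7.52e-01       FALSE
 control superficial    a.u.    8.51e-04  8.84e-04  8.51e-04 5.08e-01       FALSE
```

Reading it: the simulated bypass cohort shows a **+12.0 percentage
point** vessel oxygenation increase (the phantom's configured bypass
effect is +0.12), flagged significant by the mixed model, while the
control cohort changes by +0.14 points and is not significant —
the qualitative pattern the method is designed to detect. `mean_change`
is the unweighted mean of patient-level post-minus-pre ROI means,
`beta1` the mixed-model phase effect, and `significant` applies the
0.01 threshold to the mixed-model p-value. Perfusion and COD rows
react only marginally because the default phantom changes oxygenation,
not blood volume.

Step-by-step use of the same machinery:

```r
vis   <- read_camera("vis16")
lib   <- read_chromophores()
scene <- make_phantom(96, 96, "cabg", "pre", seed = 1)
raw   <- render_raw(forward_reflectance(scene, lib, vis), vis,
                    illumination_preset("vis_led"), noise_params(), seed = 1)
cube  <- calibrate(raw)                 # L1-normalized reflectance
maps  <- unmix_cube(cube, lib, vis)     # oxygenation / Hbrel / COD
sup   <- superficial_index(cube, vis)
keep  <- apply_cod_filter(maps, 0.7)
```

A thin command-line wrapper with `simulate` / `calibrate` / `unmix` /
`indices` / `rgb` / `analyze` / `run` subcommands is installed at
`system.file("cli", "oximap.R", package = "oximap")`.

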