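---
title: "From raw mosaic frames to oxygenation maps: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw mosaic frames to oxygenation maps: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

oximap processes intraoperative snapshot-mosaic multispectral recordings of
the exposed heart into per-pixel tissue oxygenation and perfusion maps, and
tests whether those parameters change after a coronary bypass is placed.
This vignette describes the models the package implements, the tunable
parameters and their defaults, what the phantom simulator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open.

## The measurement model

A snapshot mosaic camera carries a repeating filter tile (4x4 for the
16-band visible camera, 5x5 for the 25-band near-infrared camera) deposited
directly on the sensor, so each pixel records exactly one spectral band and
a full cube is obtained from a single exposure at reduced spatial
resolution. The calibration chain converts a raw frame into an
L1-normalized reflectance cube in five tagged stages, and every operation
checks the stage of its input:

1. **Dark subtraction** (`dark_subtract`): raw minus dark frame, clipped at
   zero. Multi-frame sequences are averaged after dark subtraction
   (`calib_config(frame = "mean")`), or a single frame can be selected.
2. **Demosaicing** (`demosaic`): each band's sparse samples are interpolated
   onto the common full-resolution grid by separable Lanczos interpolation
   (window a = 3, reflect padding), after cropping the frame to a tile
   multiple. Normalized kernel weights reproduce constants exactly and pass
   through each band's own sample sites unchanged.
3. **Bilateral denoising** (`denoise_bands`): edge-preserving filter per
   band plane. Defaults: spatial sigma 2 px, range sigma 5% of the plane's
   dynamic range. Only the filter itself is prescribed by the method; the
   sigmas are package defaults chosen to suppress shot noise without
   displacing anatomical edges, and both are exposed.
4. **Spectral correction** (`apply_correction`): each pixel's band vector
   is multiplied by the manufacturer's B x B correction matrix
   (identity when a descriptor ships none). Whether denoising runs before
   or after this step is ambiguous in the source method's wording; the
   default is denoise-then-correct, with
   `calib_config(denoise_before_correction = FALSE)` as the switch.
5. **White balancing and L1 normalization** (`estimate_illumination`,
   `to_reflectance`, `l1_normalize`): the light-source spectrum is the
   spatial mean of each band of a white-reference cube (Spectralon-type 95%
   tile processed through the identical chain). Irradiance is divided by
   this spectrum, then each pixel's spectrum is divided by the sum of its
   absolute values across bands. The L1 step removes the per-pixel global
   scale caused by camera-to-heart distance variation, which is why every
   downstream parameter is invariant to multiplying all raw frames by any
   positive constant.

**Normalization of the division spectrum.** The estimated light-source
spectrum is reported min-max normalized (`relative_power`), the usual
convention for displaying LED spectra. The division in `to_reflectance`
however uses the max-normalized curve (`power`). Dividing by a min-max
curve is ill-posed: the weakest band is forced to exactly zero, and unless
the true spectral minimum is negligible the other bands are distorted by a
band-dependent offset that is not a property of the tissue. Dividing by the
max-normalized spectrum is the exact inverse of the physical forward model
(signal proportional to reflectance times source power) and makes the
simulator round trip close exactly; when the source minimum is near zero
the two conventions coincide. A division guard floors relative power at
`1e-3` and flags the affected band in `band_flags` instead of silently
amplifying noise — relevant for NIR sources whose power rolls off beyond
850 nm.

## Beer-Lambert unmixing

On L1-normalized reflectance $r(w)$ the absorbance is $a(w) = -\log r(w)$
(natural log; reflectance floored at $10^{-6}$ before the log). Because the
coronary artery is hemoglobin-dominated, absorbance is modeled per pixel as

$$a(w) = \mu_{a,HbO_2}(w)\, c_{HbO_2} + \mu_{a,Hb}(w)\, c_{Hb} + G,$$

where $c = f \cdot L$ is the product of chromophore volume fraction and
photon path length (a.u.), and $G$ is a constant absorbing scattering
losses — and, usefully, any per-pixel rescaling of reflectance, so the L1
step biases neither the hemoglobin coefficients nor the fit quality. One
shared QR factorization of the B x 3 design solves all pixels at once by
ordinary unconstrained least squares; with 16 visible bands that is 16
equations for 3 unknowns.

Derived parameters:

* **Oxygenation** $= c_{HbO_2} / (c_{HbO_2} + c_{Hb})$, the path length
  cancels. Negative fitted coefficients are clipped at zero *at the
  reporting stage only*; the raw signed coefficients are kept in the maps
  for diagnostics. Whether to clip or report raw fractions is not
  prescribed by the method; clip-then-ratio keeps the reported value in
  [0, 1] without touching the fit itself, and the denominator guard
  ($< 10^{-12}$) marks pixels with no recoverable hemoglobin as invalid.
* **Relative hemoglobin content** $= c_{HbO_2} + c_{Hb}$ after the same
  clip, determined only up to $L$.
* **COD** $= R^2$ of the unconstrained fit, computed before any clipping.
  A zero-variance (flat) spectrum has an undefined $R^2$; it is defined as
  0 and flagged invalid, which is exactly what makes specular highlights —
  near-flat, near-unity reflectance — fail the downstream `COD >= 0.7`
  quality gate without any special-casing.
* **Perfusion indices**: ratios of mean L1-normalized absorbance,
  530–580 nm over 496–504 nm for the visible camera (superficial
  perfusion; 5 and 2 bands) and 826–928 nm over 668–739 nm for the NIR
  camera (deep perfusion; 10 and 6 bands). Band membership is inclusive of
  both endpoints by peak wavelength — the only unambiguous reading of a
  closed range — which excludes the 581 nm band (FWHM ±18 nm) from the
  530–580 nm numerator. The ~500 nm and ~797 nm denominators sit near
  isosbestic points, making the indices sensitive to hemoglobin amount
  rather than to its oxygenation.

The natural-log choice is immaterial for all reported parameters: changing
the log base rescales the coefficients and $G$ jointly, leaving
oxygenation, COD and both indices unchanged (asserted numerically in the
tests).

## ROI statistics

Pixels failing `COD >= 0.7` or any validity guard are excluded, the
segmented-vessel mask is intersected with the survivors, and each retained
pixel contributes one observation per parameter to a long table keyed by
patient, group (bypass vs control) and phase (pre vs post). The pre/post
comparison fits, per group and parameter,

$$y_{ijk} = \beta_0 + \beta_1\,[\text{phase}=\text{post}] + u_i +
\varepsilon_{ijk}, \qquad u_i \sim N(0, \sigma_u^2),$$

by REML (`lme4::lmer`), with the patient random intercept absorbing the
large between-patient baseline differences that a pooled test would count
as noise. The reported p-value is a large-sample Wald z-test on $\beta_1$;
with three to five patients this is anti-conservative, so the report also
carries a patient-level paired t-test on the per-patient mean changes as a
robustness line, and the significance threshold defaults to the stricter
0.01. Pixel-level observations are the default unit because the violin
summaries display pixel distributions; aggregating to patient means first
is available by feeding `compare_groups` a pre-aggregated table. A
boundary (singular) REML fit — $\hat\sigma_u = 0$ — is reported as a
converged fit, not a failure. No multiple-testing correction is applied
across the five parameters; none is applied in the method this package
operationalizes, and silently adding one would change its conclusions.
Oxygenation is reported in percent in tables; internal computation is in
fractions.

## The phantom simulator

Because the clinical recordings behind the method are not publicly
available, the package ships a simulator that renders ground-truth scenes
into raw sensor frames so the entire chain is testable end to end. A scene
is a curved vessel (soft partial-volume edge profile, pure core) crossing
a smoothly heterogeneous tissue background, with per-pixel $c_{HbO_2}$,
$c_{Hb}$ and $G$ maps. Defaults define the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `background_ox` | 0.50 | tissue oxygenation fraction |
| `vessel_ox_pre` | 0.60 | vessel oxygenation before bypass |
| `delta` | +0.12 | bypass-induced vessel oxygenation change |
| `patient_ox_sd` | 0.10 | between-patient baseline SD (cohorts) |
| `background_tot` / `vessel_tot` | 0.002 / 0.005 | $f \cdot L$ levels (a.u.) |
| `g_mean` | 0.20 | scattering offset |
| `vessel_width` / `vessel_edge` | 12 / 6 px | core and ramp widths |
| `n_specular` | 2 | specular highlight patches |

`delta = 0.12` matches the magnitude of the reported post-bypass
oxygenation increase (about 12 percentage points) and `patient_ox_sd =
0.10` the spread of reported pre-surgery baselines (roughly 56–73%); the
remaining levels are chosen once as physiologically plausible values that
put absorbances in the 0.3–1.5 range a visible-band tissue measurement
occupies. Both phases of a patient share one seed, hence identical spatial
fields; the bypass scenario shifts vessel oxygenation by exactly `delta`,
and the control scenario is identical across phases, so ground-truth
differences are known exactly.

Rendering inverts the calibration chain: reflectance
$\exp(-a)$ per band (monochromatic per band by default, so forward and
inverse models are consistent and round trips are exact; FWHM-weighted
rendering mirrors the `fwhm_weighted` resampling option), times the
illumination preset, times a gain that puts a 95% white tile near 80% of
the 10-bit full scale, optionally mixed through the inverse correction
matrix, mosaic-sampled, dark offset added, Poisson shot noise (33
electrons per count, about 40 dB SNR at mid-scale), Gaussian read noise,
and quantization. Specular highlights are modeled as reflectance ≈ 1
patches rather than sensor saturation, because the quality gate that must
remove them acts on spectral flatness, not on saturation.

What the simulator does **not** emulate: cardiac anatomy and myocardial
chromophores beyond hemoglobin (myoglobin, lipids, collagen), wavelength-
dependent path length and scattering (the constant-$G$ assumption is built
into both the simulator and the fit, so passing round trips cannot detect
its violation in real tissue), cardiac motion (a rigid-jitter option was
considered and left out; the clinical acquisitions mitigate motion by
frame rate), cross-camera registration, and the true vendor correction
matrix and LED spectrum (the shipped presets are synthetic stand-ins and
say so). Passing tests therefore demonstrate correctness of the
*computation*, not clinical validity of the Beer-Lambert assumptions.

The chromophore table shipped as package data
(`hemoglobin_synthetic.csv`, 450–1000 nm at 2 nm) is likewise an analytic
stand-in: a monotone cubic interpolant through hand-placed knots
reproducing the canonical whole-blood landmarks (HbO2 double peak at
542/577 nm, Hb peak at 556 nm, isosbestic crossings near 500 and 797 nm,
the Hb hump near 760 nm), generated by `synthetic_hemoglobin_spectra()`.
Any table with these qualitative features supports the self-consistent
simulation-and-recovery design; swapping in a measured compilation is a
one-file change.

## Numerical choices and degenerate inputs

* Stage tags make illegal orderings (e.g. L1-normalizing counts) hard
  errors rather than silent misuse.
* Reflectance is floored at $10^{-6}$ before the log; division by the
  illumination spectrum is floored at $10^{-3}$ relative power with the
  band flagged; L1 normalization flags all-zero pixels invalid instead of
  dividing by zero; an empty ROI after filtering is an explicit error, not
  an empty summary.
* `nearest_band` breaks ties toward the shorter wavelength. The RGB
  reconstruction requests 597/551/460 nm and lands on the 596/550/460 nm
  bands — the requested red and green wavelengths are not in the band
  list, which we read as rounding in the method description.
* Lanczos reconstruction extrapolates by reflection at the frame border;
  accuracy bounds for the round trip are therefore stated for the frame
  interior (a two-tile margin). Vessel-level summaries are asserted
  without such a margin.
* Problem sizes used by the test-suite and acceptance studies — phantoms
  of 64–128 px squared, cohorts of 3+2 patients, 20-seed noise
  replicates, 200 null and 100 alternative mixed-model replicates at 5
  patients x 200 pixels/phase — are the package's chosen desk-scale study
  conditions; they keep every property estimable (binomial tolerance on
  the type-I rate, power well away from the 0.8 bound) at interactive run
  times.

## Known limitations

The Wald z-test is optimistic for a handful of patients; treat
significance flags as indicative and read the paired t-test column
alongside. Demosaicing accuracy degrades at the frame border and at
features sharper than the mosaic pitch. The unmixing is only as meaningful
as the hemoglobin-dominance assumption; outside vessels (or under strong
specularity) the COD gate is the safeguard, and parameters from
low-light flagged bands should not be over-read. Deep-perfusion contrast
in the NIR is limited at realistic SNR — consistent with the source
method's own experience — and the shipped NIR pathway is exercised mainly
through its indices, not through unmixing.

## Worked example

```{r example}
library(oximap)

res <- run_pipeline(list(
  seed = 11,
  output_dir = "demo_out",
  simulate = list(n_cabg = 2, n_control = 2, height = 96, width = 96)
))
res$report
```

The report contains one row per group and parameter with the mean
patient-level change, the mixed-model phase effect and p-value, the paired
t-test and the significance flag at `alpha = 0.01`; `demo_out/` holds the
CSVs and a manifest with seeds, thresholds and file hashes.
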