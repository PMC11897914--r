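# Shared fixtures, memoized so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

fx_vis <- function() {
  if (is.null(.fx$vis)) .fx$vis <- read_camera("vis16")
  .fx$vis
}

fx_nir <- function() {
  if (is.null(.fx$nir)) .fx$nir <- read_camera("nir25")
  .fx$nir
}

fx_lib <- function() {
  if (is.null(.fx$lib)) .fx$lib <- read_chromophores()
  .fx$lib
}

# Small 4-band camera with a 2x2 tile for cheap structural tests.
tiny_camera <- function(peaks = c(500, 520, 540, 560), sensor = c(8, 8)) {
  camera_model("TINY", peaks, rep(10, length(peaks)),
               c(2, 2), sensor)
}

# Synthetic library whose two chromophore spectra are not collinear
# with the intercept (linear + quadratic in wavelength).
tiny_library <- function() {
  w <- seq(440, 1000, by = 4)
  chromophore_library(w, 2 + 0.001 * (w - 440),
                      1 + 1e-6 * (w - 700)^2)
}

# Noise-free rendered + calibrated VIS phantom, shared across tests.
fx_roundtrip <- function() {
  if (is.null(.fx$rt)) {
    scene <- make_phantom(64, 64, "cabg", "pre",
                          params = phantom_params(n_specular = 0,
                                                  vessel_edge = 10),
                          seed = 101)
    refl <- forward_reflectance(scene, fx_lib(), fx_vis())
    bundle <- render_raw(refl, fx_vis(), illumination_preset("vis_led"),
                         noise_off(), seed = 102)
    .fx$rt <- list(scene = scene, refl = refl, bundle = bundle,
                   cal = calibrate(bundle))
  }
  .fx$rt
}

# Build a spectral cube directly from a B x 1-pixel-per-row spec.
cube_from_planes <- function(planes, stage, peaks) {
  data <- array(NA_real_, c(dim(planes[[1]]), length(planes)))
  for (i in seq_along(planes)) data[, , i] <- planes[[i]]
  spectral_cube(data, stage, "TEST", band_peaks = peaks)
}
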