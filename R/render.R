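#' Illumination spectrum
#'
#' Relative spectral power of the light source on a wavelength grid.
#' `power` is stored normalized to its maximum (so values lie in
#' [0, 1]); `relative_power` additionally holds the min-max normalized
#' curve (minimum 0, maximum 1), the convention used when reporting an
#' estimated light-source spectrum. A spectrum that is flat within
#' `1e-9` of its mean has no meaningful min-max form and keeps
#' `relative_power = power`.
#'
#' @param wavelengths_nm Strictly increasing grid in nm.
#' @param power Non-negative relative power on the grid.
#' @return Object of class `illumination_spectrum`.
#' @export
illumination_spectrum <- function(wavelengths_nm, power) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  power <- as.numeric(power)
  stopifnot(length(wavelengths_nm) == length(power), all(power >= 0))
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  pm <- max(power)
  pnorm <- if (pm > 0) power / pm else power
  rng <- diff(range(pnorm))
  rel <- if (rng > 1e-9) (pnorm - min(pnorm)) / rng else pnorm
  structure(list(wavelengths_nm = wavelengths_nm, power = pnorm,
                 relative_power = rel, flat = rng <= 1e-9),
            class = "illumination_spectrum")
}

#' Built-in illumination presets
#'
#' `"flat"`: spectrally uniform. `"vis_led"`: broad visible LED hump
#' peaking near 540 nm. `"nir_led"`: uniform up to 850 nm then rolling
#' off linearly to 30% at 950 nm, mimicking the reduced LED power in
#' the upper NIR range. Presets are synthetic stand-ins for the (not
#' publicly available) measured source spectrum.
#'
#' @param name Preset name.
#' @return An [illumination_spectrum()] on a 400-1000 nm grid.
#' @export
illumination_preset <- function(name = c("flat", "vis_led", "nir_led")) {
  name <- match.arg(name)
  w <- seq(400, 1000, by = 2)
  p <- switch(name,
    flat = rep(1, length(w)),
    vis_led = 0.55 + 0.45 * exp(-((w - 540) / 110)^2),
    nir_led = ifelse(w <= 850, 1,
                     ifelse(w <= 950, 1 - 0.7 * (w - 850) / 100, 0.3)))
  illumination_spectrum(w, p)
}

# Max-normalized illumination power interpolated at given wavelengths.
illum_power_at <- function(illum, wavelengths_nm) {
  stopifnot(inherits(illum, "illumination_spectrum"))
  if (min(wavelengths_nm) < min(illum$wavelengths_nm) ||
      max(wavelengths_nm) > max(illum$wavelengths_nm))
    stop("requested wavelengths outside the illumination grid")
  stats::approx(illum$wavelengths_nm, illum$power, xout = wavelengths_nm)$y
}

#' Sensor noise and digitization parameters
#'
#' @param dark_level Mean dark offset in counts.
#' @param read_sd Gaussian read noise SD in counts.
#' @param electrons_per_count Conversion gain used for Poisson shot
#'   noise; the default of 33 yields roughly 40 dB SNR at mid-scale
#'   signals on a 10-bit sensor.
#' @param shot Apply Poisson shot noise?
#' @param bit_depth Quantization bit depth.
#' @return Named list of noise parameters.
#' @export
noise_params <- function(dark_level = 64, read_sd = 1,
                         electrons_per_count = 33, shot = TRUE,
                         bit_depth = 10) {
  list(dark_level = dark_level, read_sd = read_sd,
       electrons_per_count = electrons_per_count, shot = isTRUE(shot),
       bit_depth = as.integer(bit_depth))
}

#' Noise-free sensor settings
#'
#' Convenience for exact round-trip checks: no dark offset, no read or
#' shot noise, no quantization.
#' @return Noise parameter list.
#' @export
noise_off <- function() {
  p <- noise_params(dark_level = 0, read_sd = 0, shot = FALSE)
  p$quantize <- FALSE
  p
}

mosaic_band_map <- function(camera, h, w) {
  tile <- camera$mosaic_shape
  lut <- matrix(NA_integer_, tile[1L], tile[2L])
  for (i in seq_len(nrow(camera$band_to_tile)))
    lut[camera$band_to_tile[i, 1L] + 1L, camera$band_to_tile[i, 2L] + 1L] <- i
  lut[cbind(rep((seq_len(h) - 1L) %% tile[1L] + 1L, times = w),
            rep((seq_len(w) - 1L) %% tile[2L] + 1L, each = h))] |>
    matrix(h, w)
}

sample_mosaic <- function(cube_data, band_map) {
  h <- dim(cube_data)[1L]; w <- dim(cube_data)[2L]
  idx <- cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h),
               as.vector(band_map))
  matrix(cube_data[idx], h, w)
}

digitize <- function(frame, noise) {
  out <- frame
  if (noise$shot) {
    epc <- noise$electrons_per_count
    out <- stats::rpois(length(out), lambda = pmax(out, 0) * epc) / epc
    out <- matrix(out, nrow(frame), ncol(frame))
  }
  out <- out + noise$dark_level
  if (noise$read_sd > 0)
    out <- out + matrix(stats::rnorm(length(out), sd = noise$read_sd),
                        nrow(frame), ncol(frame))
  if (!isFALSE(noise$quantize))
    out <- clamp(round(out), 0, 2^noise$bit_depth - 1)
  out
}

#' Render a reflectance cube into a raw acquisition bundle
#'
#' Inverse of the calibration chain: per-band irradiance is reflectance
#' times the illumination power at the band peak times a global gain
#' (chosen so that a 95% reflectance white tile peaks near 80% of full
#' scale), optionally mixed through the inverse of the camera's
#' spectral correction matrix to emulate sensor imperfections, sampled
#' through the mosaic pattern (each pixel keeps only its own tile
#' band), offset by the dark level, and corrupted with Poisson shot
#' noise, Gaussian read noise and quantization. A matching dark frame
#' and a raw white-reference frame (flat 0.95 reflectance) are
#' generated with the same settings.
#'
#' @param cube A [spectral_cube()] at stage `"reflectance"` whose band
#'   count matches `camera`.
#' @param camera A [camera_model()].
#' @param illum An [illumination_spectrum()].
#' @param noise A [noise_params()] list ([noise_off()] for exact
#'   round trips).
#' @param seed Integer seed; frames are bit-identical for a fixed seed.
#' @param n_frames Number of raw frames in the (short) sequence.
#' @param imperfect Apply the inverse correction matrix as a simulated
#'   sensor imperfection? (No-op for the identity matrix.)
#' @return An `acquisition_bundle`: list with `raw_frames` (list of
#'   matrices), `dark_frame`, `white_raw_frame`, `camera`, `noise`,
#'   `illum`, `seed`.
#' @export
render_raw <- function(cube, camera, illum = illumination_preset("flat"),
                       noise = noise_params(), seed = 1L, n_frames = 1L,
                       imperfect = TRUE) {
  assert_stage(cube, "reflectance")
  b <- n_bands(camera)
  d <- dim(cube$data)
  if (d[3L] != b) stop("cube band count does not match camera")
  if (d[1L] < camera$mosaic_shape[1L] || d[2L] < camera$mosaic_shape[2L])
    stop("cube smaller than one mosaic tile")
  p <- illum_power_at(illum, camera$band_peaks)
  gain <- 0.8 * (2^noise$bit_depth - 1) / 0.95
  mix <- NULL
  if (imperfect && !isTRUE(all.equal(camera$correction_matrix, diag(b)))) {
    mix <- tryCatch(solve(camera$correction_matrix),
                    error = function(e) stop("correction matrix is singular"))
  }
  band_map <- mosaic_band_map(camera, d[1L], d[2L])

  render_one <- function(refl_data) {
    irr <- sweep(refl_data, 3L, p * gain, "*")
    if (!is.null(mix)) {
      m <- mix %*% flatten_bands(irr)
      irr <- unflatten_bands(m, d[1L], d[2L])
    }
    sample_mosaic(irr, band_map)
  }

  scene_mean <- render_one(cube$data)
  white_mean <- render_one(array(0.95, d))
  with_seed(seed, {
    raw_frames <- lapply(seq_len(n_frames), function(i) digitize(scene_mean, noise))
    dark_noise <- noise
    dark_frame <- digitize(matrix(0, d[1L], d[2L]), dark_noise)
    white_raw_frame <- digitize(white_mean, noise)
    structure(list(raw_frames = raw_frames, dark_frame = dark_frame,
                   white_raw_frame = white_raw_frame, camera = camera,
                   noise = noise, illum = illum, seed = seed),
              class = "acquisition_bundle")
  })
}

#' @export
print.acquisition_bundle <- function(x, ...) {
  d <- dim(x$raw_frames[[1L]])
  cat(sprintf("acquisition_bundle: %d frame(s) %d x %d, camera %s, seed %d\n",
              length(x$raw_frames), d[1L], d[2L], x$camera$name, x$seed))
  invisible(x)
}
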