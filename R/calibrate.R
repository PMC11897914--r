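#' Dark-frame subtraction
#'
#' Element-wise `raw - dark`, clipped at zero.
#'
#' @param raw,dark Numeric matrices of equal shape.
#' @return Real matrix of dark-corrected counts.
#' @export
dark_subtract <- function(raw, dark) {
  if (!all(dim(raw) == dim(dark)))
    stop("raw and dark frames must have the same shape")
  pmax(raw - dark, 0)
}

# Lanczos kernel, window parameter a.
lanczos_kernel <- function(x, a = 3) {
  out <- numeric(length(x))
  nz <- abs(x) < a & x != 0
  out[x == 0] <- 1
  out[nz] <- a * sin(pi * x[nz]) * sin(pi * x[nz] / a) / (pi^2 * x[nz]^2)
  out
}

# Mirror an out-of-range 0-based sample index into [0, n-1].
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(0L, length(j)))
  p <- 2L * (n - 1L)
  j <- ((j %% p) + p) %% p
  ifelse(j > n - 1L, p - j, j)
}

# Dense interpolation matrix mapping n decimated samples (at 0-based
# full-grid positions offset, offset + step, ...) onto n_out full-grid
# positions, using a Lanczos kernel with reflect padding. Weights are
# renormalized per output position so constants are reproduced exactly.
lanczos_matrix <- function(n_out, offset, step, a = 3) {
  n <- length(seq(offset + 1L, n_out, by = step))
  M <- matrix(0, n_out, n)
  for (y in seq_len(n_out)) {
    u <- (y - 1L - offset) / step      # position in sample units
    k0 <- floor(u)
    taps <- (k0 - a + 1L):(k0 + a)
    wt <- lanczos_kernel(u - taps, a)
    wt <- wt / sum(wt)
    idx <- reflect_index(taps, n) + 1L
    for (t in seq_along(taps)) M[y, idx[t]] <- M[y, idx[t]] + wt[t]
  }
  M
}

#' Demosaic a raw frame into a band cube
#'
#' Each band of a snapshot mosaic sensor is sampled on a sparse regular
#' subgrid (one pixel per repeating filter tile). Demosaicing transfers
#' all bands to the common full-resolution pixel grid by separable
#' Lanczos interpolation (window a = 3, reflect padding), after
#' cropping the frame to the largest multiple of the tile size.
#'
#' @param frame Numeric matrix (a dark-subtracted raw frame).
#' @param camera A [camera_model()] describing the mosaic layout.
#' @param a Lanczos window parameter.
#' @return A [spectral_cube()] at stage `"counts"` with the cropped
#'   spatial size.
#' @export
demosaic <- function(frame, camera, a = 3) {
  stopifnot(inherits(camera, "camera_model"))
  tile <- camera$mosaic_shape
  h <- tile[1L] * (nrow(frame) %/% tile[1L])
  w <- tile[2L] * (ncol(frame) %/% tile[2L])
  if (h < tile[1L] || w < tile[2L]) stop("frame smaller than one mosaic tile")
  frame <- frame[seq_len(h), seq_len(w), drop = FALSE]
  My <- lapply(seq_len(tile[1L]) - 1L, function(o) lanczos_matrix(h, o, tile[1L], a))
  Mx <- lapply(seq_len(tile[2L]) - 1L, function(o) lanczos_matrix(w, o, tile[2L], a))
  b <- n_bands(camera)
  data <- array(NA_real_, c(h, w, b))
  for (i in seq_len(b)) {
    tr <- camera$band_to_tile[i, 1L]
    tc <- camera$band_to_tile[i, 2L]
    s <- frame[seq(tr + 1L, h, by = tile[1L]), seq(tc + 1L, w, by = tile[2L]),
               drop = FALSE]
    data[, , i] <- My[[tr + 1L]] %*% s %*% t(Mx[[tc + 1L]])
  }
  spectral_cube(data, "counts", camera)
}

# Bilateral filter of one plane: Gaussian spatial window (radius
# 2 * sigma_spatial) weighted by a Gaussian on intensity difference.
bilateral_plane <- function(plane, sigma_spatial, sigma_range) {
  if (sigma_range <= 0) return(plane)
  r <- max(1L, ceiling(2 * sigma_spatial))
  h <- nrow(plane); w <- ncol(plane)
  ry <- reflect_index(seq(-r, h - 1L + r), h) + 1L
  rx <- reflect_index(seq(-r, w - 1L + r), w) + 1L
  pad <- plane[ry, rx, drop = FALSE]
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (dy in -r:r) for (dx in -r:r) {
    ws <- exp(-(dy^2 + dx^2) / (2 * sigma_spatial^2))
    shifted <- pad[(1L + r + dy):(h + r + dy), (1L + r + dx):(w + r + dx)]
    wt <- ws * exp(-(shifted - plane)^2 / (2 * sigma_range^2))
    num <- num + wt * shifted
    den <- den + wt
  }
  num / den
}

#' Edge-preserving denoising of band planes
#'
#' Applies a bilateral filter independently to every band plane. The
#' range sigma defaults to 5% of each plane's dynamic range; constant
#' planes pass through unchanged.
#'
#' @param cube A [spectral_cube()] at stage `"counts"` or
#'   `"irradiance"`.
#' @param sigma_spatial Spatial Gaussian SD in pixels.
#' @param sigma_range Intensity Gaussian SD, in the plane's units;
#'   `NULL` for the 5% default.
#' @return Cube of the same stage, denoised.
#' @export
denoise_bands <- function(cube, sigma_spatial = 2, sigma_range = NULL) {
  assert_stage(cube, c("counts", "irradiance"))
  stopifnot(sigma_spatial > 0, is.null(sigma_range) || sigma_range > 0)
  out <- cube
  for (i in seq_len(dim(cube$data)[3L])) {
    plane <- cube$data[, , i]
    sr <- if (is.null(sigma_range)) 0.05 * diff(range(plane)) else sigma_range
    out$data[, , i] <- bilateral_plane(plane, sigma_spatial, sr)
  }
  out
}

#' Apply the spectral correction matrix
#'
#' Replaces each pixel's band vector by `matrix %*% vector`,
#' compensating sensor-specific spectral imperfections. Promotes the
#' cube from `"counts"` to `"irradiance"`.
#'
#' @param cube A [spectral_cube()] at stage `"counts"`.
#' @param matrix B x B correction matrix (the camera's by default when
#'   a [camera_model()] is given).
#' @return Cube at stage `"irradiance"`.
#' @export
apply_correction <- function(cube, matrix) {
  assert_stage(cube, "counts")
  if (inherits(matrix, "camera_model")) matrix <- matrix$correction_matrix
  b <- dim(cube$data)[3L]
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(b, b)))
    stop("correction matrix must be ", b, " x ", b)
  d <- dim(cube$data)
  out <- cube
  out$data <- unflatten_bands(matrix %*% flatten_bands(cube$data), d[1L], d[2L])
  out$stage <- "irradiance"
  out
}

#' Estimate the light-source spectrum from a white-reference cube
#'
#' Averages all pixels of each band of a fully processed white-tile
#' cube. The resulting per-band means define the illumination spectrum:
#' `relative_power` is the min-max normalized curve (the reporting
#' convention) while the division spectrum used for white balancing is
#' normalized to its maximum, which keeps the division well-defined at
#' the weakest band. A white cube carrying essentially no light is a
#' degenerate-spectrum error.
#'
#' @param white_cube A [spectral_cube()] at stage `"irradiance"` from
#'   the white-reference frame.
#' @return An [illumination_spectrum()] sampled at the camera band
#'   peaks.
#' @export
estimate_illumination <- function(white_cube) {
  assert_stage(white_cube, "irradiance")
  means <- apply(white_cube$data, 3L, mean)
  if (max(means) <= 0)
    stop("degenerate white-reference spectrum: no light recorded")
  illumination_spectrum(white_cube$band_peaks, means)
}

#' Convert irradiance to reflectance by white balancing
#'
#' Divides every pixel's band vector by the illumination spectrum
#' (max-normalized) at the camera bands. Bands whose relative power
#' falls below `floor` are floored at `floor` and flagged in
#' `band_flags` rather than silently amplified: with strong spectral
#' roll-off (e.g. NIR illumination dropping beyond 850 nm) low-light
#' bands must degrade gracefully, not explode.
#'
#' @param cube A [spectral_cube()] at stage `"irradiance"`.
#' @param illum An [illumination_spectrum()].
#' @param floor Division guard on relative power.
#' @return Cube at stage `"reflectance"` (values clipped at 0).
#' @export
to_reflectance <- function(cube, illum, floor = 1e-3) {
  assert_stage(cube, "irradiance")
  p <- illum_power_at(illum, cube$band_peaks)
  flagged <- p < floor
  p <- pmax(p, floor)
  out <- cube
  out$data <- pmax(sweep(cube$data, 3L, p, "/"), 0)
  out$stage <- "reflectance"
  out$band_flags <- out$band_flags | flagged
  out
}

#' Per-pixel L1 normalization of reflectance spectra
#'
#' Divides each pixel's band vector by the sum of absolute reflectance
#' values across bands, removing the global scale caused by variations
#' in camera-to-tissue distance. Pixels with an all-zero spectrum are
#' flagged invalid (output zeros), not errors.
#'
#' @param cube A [spectral_cube()] at stage `"reflectance"`.
#' @return Cube at stage `"l1_reflectance"`; per-pixel L1 norms are 1
#'   on valid pixels.
#' @export
l1_normalize <- function(cube) {
  assert_stage(cube, "reflectance")
  d <- dim(cube$data)
  s <- apply(abs(cube$data), c(1L, 2L), sum)
  ok <- s > 0
  s[!ok] <- 1
  out <- cube
  out$data <- sweep(cube$data, c(1L, 2L), s, "/")
  out$data[array(rep(!ok, d[3L]), d)] <- 0
  out$stage <- "l1_reflectance"
  out$valid <- cube$valid & ok
  out
}

#' Calibration configuration
#'
#' @param denoise Apply the bilateral filter?
#' @param sigma_spatial,sigma_range Bilateral filter parameters, see
#'   [denoise_bands()].
#' @param denoise_before_correction Filter band planes before (default)
#'   or after the spectral correction matrix.
#' @param frame `"mean"` to average all dark-subtracted frames of a
#'   bundle, or a 1-based frame index.
#' @return Named configuration list.
#' @export
calib_config <- function(denoise = TRUE, sigma_spatial = 2,
                         sigma_range = NULL,
                         denoise_before_correction = TRUE,
                         frame = "mean") {
  list(denoise = isTRUE(denoise), sigma_spatial = sigma_spatial,
       sigma_range = sigma_range,
       denoise_before_correction = isTRUE(denoise_before_correction),
       frame = frame)
}

#' Full radiometric calibration of an acquisition bundle
#'
#' Runs the complete chain on raw mosaic frames: dark subtraction,
#' (optional) temporal averaging, Lanczos demosaicing, bilateral
#' denoising, spectral correction, light-source estimation from the
#' white-reference frame (processed through the identical chain),
#' white balancing and per-pixel L1 normalization.
#'
#' @param bundle An `acquisition_bundle` (from [render_raw()] or
#'   [read_bundle()]), containing raw frame(s), a dark frame and a
#'   white-reference frame.
#' @param camera A [camera_model()]; defaults to the bundle's camera.
#' @param config A [calib_config()] list.
#' @return A [spectral_cube()] at stage `"l1_reflectance"`, with the
#'   estimated [illumination_spectrum()] attached as element `illum`.
#' @export
calibrate <- function(bundle, camera = NULL, config = calib_config()) {
  if (!inherits(bundle, "acquisition_bundle"))
    stop("expected an acquisition_bundle")
  if (is.null(camera)) camera <- bundle$camera
  if (is.null(bundle$raw_frames) || !length(bundle$raw_frames))
    stop("bundle is missing raw frames")
  if (is.null(bundle$dark_frame)) stop("bundle is missing the dark frame")
  if (is.null(bundle$white_raw_frame))
    stop("bundle is missing the white-reference frame")

  subbed <- lapply(bundle$raw_frames, dark_subtract, dark = bundle$dark_frame)
  frame <- if (identical(config$frame, "mean")) {
    Reduce(`+`, subbed) / length(subbed)
  } else {
    i <- as.integer(config$frame)
    if (i < 1L || i > length(subbed)) stop("frame index out of range")
    subbed[[i]]
  }

  process <- function(fr) {
    cube <- demosaic(fr, camera)
    if (config$denoise && config$denoise_before_correction)
      cube <- denoise_bands(cube, config$sigma_spatial, config$sigma_range)
    cube <- apply_correction(cube, camera)
    if (config$denoise && !config$denoise_before_correction) {
      cube <- denoise_bands(cube, config$sigma_spatial, config$sigma_range)
    }
    cube
  }

  scene <- process(frame)
  white <- process(dark_subtract(bundle$white_raw_frame, bundle$dark_frame))
  illum <- estimate_illumination(white)
  out <- l1_normalize(to_reflectance(scene, illum))
  out$illum <- illum
  out
}
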