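#' Band-resolved image cube with a processing-stage tag
#'
#' A `spectral_cube` is a height x width x bands numeric array plus the
#' stage it has reached in the calibration chain. Stages are ordered:
#' `counts` (dark-subtracted, demosaicked sensor counts), `irradiance`
#' (after spectral correction), `reflectance` (after white balancing),
#' `l1_reflectance` (per-pixel L1-normalized reflectance) and
#' `absorbance` (-log of L1 reflectance). Every operation checks the
#' stage of its input, so cubes cannot silently skip a step.
#'
#' @param data Numeric H x W x B array.
#' @param stage One of `"counts"`, `"irradiance"`, `"reflectance"`,
#'   `"l1_reflectance"`, `"absorbance"`.
#' @param camera A [camera_model()] or a camera name; band peaks are
#'   copied onto the cube.
#' @param band_peaks Band peak wavelengths; required when `camera` is
#'   just a name.
#' @param valid Optional H x W logical matrix of per-pixel validity
#'   (default all `TRUE`).
#' @param band_flags Optional length-B logical vector marking bands that
#'   were guarded during processing (e.g. near-zero illumination).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, stage, camera, band_peaks = NULL,
                          valid = NULL, band_flags = NULL) {
  stage <- match.arg(stage, c("counts", "irradiance", "reflectance",
                              "l1_reflectance", "absorbance"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("cube data must be a 3-d array (height x width x bands)")
  if (inherits(camera, "camera_model")) {
    band_peaks <- camera$band_peaks
    camera <- camera$name
  }
  if (is.null(band_peaks))
    stop("band_peaks required when camera is given by name")
  if (dim(data)[3L] != length(band_peaks))
    stop("cube has ", dim(data)[3L], " bands but ", length(band_peaks),
         " band peaks were given")
  if (stage == "reflectance" && any(data < 0, na.rm = TRUE))
    stop("reflectance values must be non-negative")
  if (is.null(valid)) valid <- matrix(TRUE, dim(data)[1L], dim(data)[2L])
  if (is.null(band_flags)) band_flags <- rep(FALSE, dim(data)[3L])
  structure(list(data = data, stage = stage, camera_ref = camera,
                 band_peaks = as.numeric(band_peaks),
                 valid = valid, band_flags = band_flags),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("spectral_cube [%s]: %d x %d px, %d bands (%s), %d invalid px\n",
              x$stage, d[1L], d[2L], d[3L], x$camera_ref, sum(!x$valid)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

assert_stage <- function(cube, stages) {
  if (!inherits(cube, "spectral_cube"))
    stop("expected a spectral_cube")
  if (!cube$stage %in% stages)
    stop("cube is at stage '", cube$stage, "' but stage ",
         paste(sQuote(stages), collapse = " or "), " is required")
  invisible(cube)
}

# Flatten a cube to a B x Npix matrix of band vectors (pixels in
# column-major spatial order); inverse of unflatten_bands.
flatten_bands <- function(cube_data) {
  d <- dim(cube_data)
  t(matrix(cube_data, d[1L] * d[2L], d[3L]))
}

unflatten_bands <- function(mat, h, w) {
  array(t(mat), dim = c(h, w, nrow(mat)))
}
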