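#' Snapshot mosaic camera description
#'
#' A `camera_model` captures the spectral and geometric layout of one
#' snapshot mosaic multispectral camera: the peak wavelength and FWHM of
#' every band, the repeating filter tile, the sensor size, the mapping
#' from band index to tile position, and an optional band-space
#' correction matrix supplied by the manufacturer.
#'
#' @param name Short text label, e.g. `"VIS"` or `"NIR"`.
#' @param band_peaks Numeric vector of band center wavelengths in nm,
#'   strictly increasing.
#' @param band_fwhm Numeric vector of band FWHM in nm, same length as
#'   `band_peaks`.
#' @param mosaic_shape Integer vector `c(rows, cols)` of the repeating
#'   filter tile; `rows * cols` must equal the number of bands.
#' @param sensor_shape Integer vector `c(height, width)` in pixels.
#' @param band_to_tile Integer matrix with one row per band giving the
#'   0-based `(tile_row, tile_col)` of that band inside the tile, or
#'   `NULL` for the default row-major layout in ascending wavelength.
#' @param correction_matrix Square B x B matrix applied to band vectors
#'   during calibration, or `NULL` for the identity.
#'
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(name, band_peaks, band_fwhm, mosaic_shape,
                         sensor_shape, band_to_tile = NULL,
                         correction_matrix = NULL) {
  band_peaks <- as.numeric(band_peaks)
  band_fwhm <- as.numeric(band_fwhm)
  mosaic_shape <- as.integer(mosaic_shape)
  sensor_shape <- as.integer(sensor_shape)
  b <- length(band_peaks)
  if (length(band_fwhm) != b)
    stop("band_peaks and band_fwhm must have the same length")
  if (length(mosaic_shape) != 2L || any(mosaic_shape < 1L))
    stop("mosaic_shape must be two positive integers")
  if (b != prod(mosaic_shape))
    stop("number of bands (", b, ") must equal mosaic rows x cols (",
         prod(mosaic_shape), ")")
  if (b > 1 && any(diff(band_peaks) <= 0))
    stop("band_peaks must be strictly increasing")
  if (length(sensor_shape) != 2L || any(sensor_shape < mosaic_shape))
    stop("sensor_shape must be at least one mosaic tile")
  if (is.null(band_to_tile)) {
    # row-major, ascending wavelength
    band_to_tile <- cbind(
      tile_row = (seq_len(b) - 1L) %/% mosaic_shape[2L],
      tile_col = (seq_len(b) - 1L) %% mosaic_shape[2L]
    )
  } else {
    band_to_tile <- matrix(as.integer(band_to_tile), ncol = 2L,
                           dimnames = list(NULL, c("tile_row", "tile_col")))
    if (nrow(band_to_tile) != b)
      stop("band_to_tile must have one row per band")
    key <- band_to_tile[, 1L] * mosaic_shape[2L] + band_to_tile[, 2L]
    if (any(band_to_tile[, 1L] < 0L) || any(band_to_tile[, 1L] >= mosaic_shape[1L]) ||
        any(band_to_tile[, 2L] < 0L) || any(band_to_tile[, 2L] >= mosaic_shape[2L]) ||
        anyDuplicated(key))
      stop("band_to_tile must be a bijection onto the tile positions")
  }
  if (is.null(correction_matrix)) {
    correction_matrix <- diag(b)
  } else {
    correction_matrix <- as.matrix(correction_matrix)
    if (!all(dim(correction_matrix) == c(b, b)))
      stop("correction_matrix must be ", b, " x ", b)
  }
  structure(
    list(name = name, band_peaks = band_peaks, band_fwhm = band_fwhm,
         mosaic_shape = mosaic_shape, sensor_shape = sensor_shape,
         band_to_tile = band_to_tile, correction_matrix = correction_matrix),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model '%s': %d bands, %.0f-%.0f nm, %dx%d tile, %dx%d sensor\n",
              x$name, n_bands(x), min(x$band_peaks), max(x$band_peaks),
              x$mosaic_shape[1L], x$mosaic_shape[2L],
              x$sensor_shape[1L], x$sensor_shape[2L]))
  invisible(x)
}

n_bands <- function(camera) length(camera$band_peaks)

#' Load a camera descriptor from YAML
#'
#' Reads a camera descriptor file with fields `name`, `band_peaks`,
#' `band_fwhm`, `mosaic_shape`, `sensor_shape`, optional `band_to_tile`
#' (list of `[tile_row, tile_col]` pairs, 0-based) and optional
#' `correction_matrix` (path to a headerless CSV matrix, relative to the
#' descriptor). Two descriptors ship with the package: `"vis16"` (16
#' bands, 460-600 nm, 4x4 tile) and `"nir25"` (25 bands, 659-947 nm,
#' 5x5 tile).
#'
#' @param path Path to the YAML descriptor, or one of the shipped names
#'   `"vis16"` / `"nir25"`.
#' @return A [camera_model()].
#' @export
#' @examples
#' vis <- read_camera("vis16")
#' nearest_band(vis, 551)
read_camera <- function(path) {
  if (path %in% c("vis16", "nir25"))
    path <- system.file("extdata", paste0(path, ".yaml"), package = "oximap",
                        mustWork = TRUE)
  if (!file.exists(path)) stop("camera descriptor not found: ", path)
  d <- yaml::read_yaml(path)
  req <- c("name", "band_peaks", "band_fwhm", "mosaic_shape", "sensor_shape")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("camera descriptor missing fields: ",
                         paste(miss, collapse = ", "))
  b2t <- if (!is.null(d$band_to_tile))
    do.call(rbind, lapply(d$band_to_tile, as.integer)) else NULL
  cm <- NULL
  if (!is.null(d$correction_matrix)) {
    mpath <- file.path(dirname(path), d$correction_matrix)
    if (!file.exists(mpath)) stop("correction matrix file not found: ", mpath)
    cm <- as.matrix(utils::read.csv(mpath, header = FALSE))
    dimnames(cm) <- NULL
  }
  camera_model(d$name, d$band_peaks, d$band_fwhm, d$mosaic_shape,
               d$sensor_shape, band_to_tile = b2t, correction_matrix = cm)
}

#' Bands whose peak falls in a wavelength range
#'
#' Band membership is decided by the peak wavelength, inclusive on both
#' endpoints. Used to select the numerator/denominator bands of the
#' superficial and deep perfusion indices.
#'
#' @param camera A [camera_model()].
#' @param lo_nm,hi_nm Range endpoints in nm, `lo_nm <= hi_nm`.
#' @return Integer vector of band indices (1-based) in increasing
#'   wavelength order; may be empty.
#' @export
bands_in_range <- function(camera, lo_nm, hi_nm) {
  stopifnot(inherits(camera, "camera_model"), lo_nm <= hi_nm)
  which(camera$band_peaks >= lo_nm & camera$band_peaks <= hi_nm)
}

#' Band with peak nearest a target wavelength
#'
#' Ties are broken toward the shorter wavelength. Used to pick the RGB
#' reconstruction channels (597, 551, 460 nm for the VIS camera).
#'
#' @param camera A [camera_model()].
#' @param wavelength_nm Positive target wavelength in nm.
#' @return A single 1-based band index.
#' @export
nearest_band <- function(camera, wavelength_nm) {
  stopifnot(inherits(camera, "camera_model"), wavelength_nm > 0)
  d <- abs(camera$band_peaks - wavelength_nm)
  # which.min returns the first minimum; peaks are ascending, so the
  # first minimum is the shorter-wavelength side of a tie
  which.min(d)
}
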