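# File formats: 16-bit TIFF for integer frames, scaled float32 TIFF
# pages + YAML sidecar for cubes and maps, YAML for descriptors and
# manifests.

write_frame_tiff <- function(m, path) {
  if (any(m < 0) || any(m > 65535))
    stop("frame values must lie in 0..65535 for 16-bit storage")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_frame_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Write an acquisition bundle to a directory
#'
#' Layout: `raw.tif` (multi-page, one page per frame), `dark.tif`,
#' `white.tif`, and a `bundle.yaml` sidecar holding the camera
#' descriptor, noise parameters and seed. Frames are stored as 16-bit
#' integer TIFF.
#'
#' @param bundle An `acquisition_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "acquisition_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(lapply(bundle$raw_frames, function(f) f / 65535),
                  file.path(dir, "raw.tif"), bits.per.sample = 16L)
  write_frame_tiff(bundle$dark_frame, file.path(dir, "dark.tif"))
  write_frame_tiff(bundle$white_raw_frame, file.path(dir, "white.tif"))
  cam <- bundle$camera
  meta <- list(
    camera = list(name = cam$name, band_peaks = cam$band_peaks,
                  band_fwhm = cam$band_fwhm,
                  mosaic_shape = cam$mosaic_shape,
                  sensor_shape = cam$sensor_shape,
                  band_to_tile = lapply(seq_len(nrow(cam$band_to_tile)),
                                        function(i) unname(cam$band_to_tile[i, ]))),
    noise = bundle$noise, seed = bundle$seed,
    n_frames = length(bundle$raw_frames))
  if (!isTRUE(all.equal(cam$correction_matrix, diag(n_bands(cam))))) {
    utils::write.table(cam$correction_matrix,
                       file.path(dir, "correction.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    meta$camera$correction_matrix <- "correction.csv"
  }
  yaml::write_yaml(meta, file.path(dir, "bundle.yaml"))
  invisible(dir)
}

#' Read an acquisition bundle from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return An `acquisition_bundle`.
#' @export
read_bundle <- function(dir) {
  ypath <- file.path(dir, "bundle.yaml")
  if (!file.exists(ypath)) stop("no bundle.yaml in ", dir)
  meta <- yaml::read_yaml(ypath)
  cm <- NULL
  if (!is.null(meta$camera$correction_matrix)) {
    cm <- as.matrix(utils::read.csv(
      file.path(dir, meta$camera$correction_matrix), header = FALSE))
    dimnames(cm) <- NULL
  }
  cam <- camera_model(meta$camera$name, meta$camera$band_peaks,
                      meta$camera$band_fwhm, meta$camera$mosaic_shape,
                      meta$camera$sensor_shape,
                      band_to_tile = do.call(rbind, meta$camera$band_to_tile),
                      correction_matrix = cm)
  raw <- tiff::readTIFF(file.path(dir, "raw.tif"), all = TRUE, as.is = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  structure(list(raw_frames = raw,
                 dark_frame = read_frame_tiff(file.path(dir, "dark.tif")),
                 white_raw_frame = read_frame_tiff(file.path(dir, "white.tif")),
                 camera = cam, noise = meta$noise, illum = NULL,
                 seed = meta$seed),
            class = "acquisition_bundle")
}

# Affine-scale a matrix into [0,1] for float32 TIFF storage.
scale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  s <- if (hi > lo) hi - lo else 1
  list(data = (m - lo) / s, lo = lo, hi = hi)
}

#' Write a spectral cube as float32 TIFF pages plus a YAML sidecar
#'
#' One page per band, affine-rescaled into [0, 1] for storage; the
#' per-cube scale, stage tag, band peaks, flags and validity mask are
#' recorded in the sidecar (`<path>.yaml`). Round trips are exact to
#' float32 precision.
#'
#' @param cube A [spectral_cube()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  lo <- min(cube$data); hi <- max(cube$data)
  s <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3L]), function(i) (cube$data[, , i] - lo) / s)
  pages <- c(pages, list((cube$valid) * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(stage = cube$stage, camera_ref = cube$camera_ref,
                        band_peaks = cube$band_peaks,
                        band_flags = cube$band_flags,
                        scale_lo = lo, scale_hi = hi, n_bands = d[3L]),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a spectral cube written by [write_cube()]
#'
#' @param path TIFF path with its `.yaml` sidecar alongside.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bands + 1L)
    stop("TIFF has ", length(pages), " pages but sidecar declares ",
         meta$n_bands, " bands (+1 validity page)")
  s <- if (meta$scale_hi > meta$scale_lo) meta$scale_hi - meta$scale_lo else 1
  d1 <- dim(pages[[1L]])
  data <- array(NA_real_, c(d1[1L], d1[2L], meta$n_bands))
  for (i in seq_len(meta$n_bands))
    data[, , i] <- pages[[i]] * s + meta$scale_lo
  spectral_cube(data, meta$stage, meta$camera_ref,
                band_peaks = meta$band_peaks,
                valid = pages[[meta$n_bands + 1L]] > 0.5,
                band_flags = as.logical(meta$band_flags))
}

#' Read a binary ROI mask
#'
#' Single-channel TIFF or PNG; any nonzero pixel belongs to the ROI.
#' PNG support requires the `png` package.
#'
#' @param path Image path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG masks requires the 'png' package")
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m != 0
}

#' Write a binary mask as TIFF
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask != 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write ground-truth scene maps and masks
#'
#' Stores the chromophore coefficient maps (`c_hbo2`, `c_hb`,
#' `g_offset`) as scaled float32 TIFF pages, the vessel and specular
#' masks as single-page TIFFs, and a YAML sidecar with the scene
#' metadata and scaling.
#'
#' @param scene A [make_phantom()] scene.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maps <- list(c_hbo2 = scene$c_hbo2, c_hb = scene$c_hb,
               g_offset = scene$g_offset)
  scaled <- lapply(maps, scale01)
  tiff::writeTIFF(lapply(scaled, `[[`, "data"),
                  file.path(dir, "coefficients.tif"), bits.per.sample = 32L)
  write_mask(scene$vessel_mask, file.path(dir, "vessel_mask.tif"))
  write_mask(scene$specular_mask, file.path(dir, "specular_mask.tif"))
  yaml::write_yaml(list(
    height = scene$height, width = scene$width, scenario = scene$scenario,
    phase = scene$phase, patient_id = scene$patient_id, group = scene$group,
    seed = scene$seed,
    scales = lapply(scaled, function(s) list(lo = s$lo, hi = s$hi))),
    file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Write a run manifest
#'
#' Records tool version, seeds, stage parameters and MD5 hashes of the
#' listed files, so that a run can be audited and reproduced.
#'
#' @param params Named list of run parameters (seeds, thresholds, ...).
#' @param files Character vector of file paths to hash.
#' @param path Output YAML path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(params, files, path) {
  files <- files[file.exists(files)]
  manifest <- list(
    tool = "oximap",
    version = as.character(utils::packageVersion("oximap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    inputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                     basename(files))))
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
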