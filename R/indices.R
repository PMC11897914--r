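# Perfusion indices from band-averaged absorbance, and the synthetic
# RGB reconstruction.

# Ratio of mean absorbance over two wavelength ranges, per pixel.
band_ratio_index <- function(cube, camera, num_range, den_range,
                             den_floor = 1e-9) {
  assert_stage(cube, c("l1_reflectance", "absorbance"))
  if (cube$stage != "absorbance") cube <- absorbance(cube)
  num_idx <- bands_in_range(camera, num_range[1L], num_range[2L])
  den_idx <- bands_in_range(camera, den_range[1L], den_range[2L])
  if (!length(num_idx) || !length(den_idx))
    stop(sprintf("camera '%s' has no bands in %g-%g nm", camera$name,
                 if (!length(num_idx)) num_range[1L] else den_range[1L],
                 if (!length(num_idx)) num_range[2L] else den_range[2L]))
  mean_over <- function(idx) {
    sub <- cube$data[, , idx, drop = FALSE]
    apply(sub, c(1L, 2L), mean)
  }
  num <- mean_over(num_idx)
  den <- mean_over(den_idx)
  out <- num / den
  out[den < den_floor | !cube$valid] <- NA_real_
  out
}

#' Superficial perfusion index (visible camera)
#'
#' Ratio of mean L1-normalized absorbance over 530-580 nm (hemoglobin
#' absorption peaks) to that over 496-504 nm (around the ~500 nm
#' isosbestic point), a tissue-hemoglobin-type index for the visible
#' camera's shallow penetration depth. On the shipped 16-band visible
#' camera the numerator selects 5 bands and the denominator 2.
#'
#' @param cube A [spectral_cube()] at stage `"l1_reflectance"` (or
#'   `"absorbance"`).
#' @param camera A [camera_model()] covering both ranges.
#' @return H x W matrix in a.u.; `NA` where invalid or the denominator
#'   underflows.
#' @export
superficial_index <- function(cube, camera) {
  band_ratio_index(cube, camera, c(530, 580), c(496, 504))
}

#' Deep perfusion index (near-infrared camera)
#'
#' Ratio of mean L1-normalized absorbance over 826-928 nm to that over
#' 668-739 nm, an NIR perfusion-type index exploiting the deeper
#' penetration of near-infrared light. On the shipped 25-band NIR
#' camera the numerator selects 10 bands and the denominator 6.
#'
#' @inheritParams superficial_index
#' @return H x W matrix in a.u.
#' @export
deep_index <- function(cube, camera) {
  band_ratio_index(cube, camera, c(826, 928), c(668, 739))
}

# Histogram equalization of a numeric vector to 0..255.
equalize_255 <- function(v) {
  n <- length(v)
  if (n <= 1L) return(rep(0L, n))
  r <- rank(v, ties.method = "average")
  as.integer(floor((r - 1) / (n - 1) * 255))
}

#' Synthetic RGB reconstruction
#'
#' Builds a familiar color image from a visible-range cube by assigning
#' the bands nearest 597, 551 and 460 nm to the red, green and blue
#' channels and applying per-channel histogram equalization to 8 bits.
#'
#' @param cube A [spectral_cube()].
#' @param camera A [camera_model()] (visible-range intended).
#' @return H x W x 3 integer array with values in 0..255.
#' @export
reconstruct_rgb <- function(cube, camera) {
  stopifnot(inherits(cube, "spectral_cube"))
  chans <- vapply(c(597, 551, 460), function(w) nearest_band(camera, w),
                  integer(1))
  d <- dim(cube$data)
  out <- array(0L, c(d[1L], d[2L], 3L))
  for (k in 1:3)
    out[, , k] <- matrix(equalize_255(as.vector(cube$data[, , chans[k]])),
                         d[1L], d[2L])
  out
}
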