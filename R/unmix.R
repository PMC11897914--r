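#' Absorbance transform
#'
#' `a = -log(r)` (natural log) per element. Reflectance is floored at
#' `1e-6` before the log; floored pixels are recorded in the `floored`
#' element of the returned cube. Accepts either plain reflectance or
#' L1-normalized reflectance; per-pixel rescaling of reflectance only
#' shifts the absorbance by a per-pixel constant, which the unmixing
#' absorbs into its intercept.
#'
#' @param cube A [spectral_cube()] at stage `"reflectance"` or
#'   `"l1_reflectance"`.
#' @return Cube at stage `"absorbance"`.
#' @export
absorbance <- function(cube) {
  assert_stage(cube, c("reflectance", "l1_reflectance"))
  out <- cube
  floored <- apply(cube$data < 1e-6, c(1L, 2L), any)
  out$data <- -log(pmax(cube$data, 1e-6))
  out$stage <- "absorbance"
  out$floored <- floored
  out
}

#' Unmix a single absorbance spectrum
#'
#' Ordinary (unconstrained) linear least squares of the absorbance
#' spectrum on the two hemoglobin absorption spectra plus an intercept:
#' `a(w) ~ mu_HbO2(w) * c_hbo2 + mu_Hb(w) * c_hb + G`. The goodness of
#' fit is the coefficient of determination `R^2 = 1 - SS_res/SS_tot`;
#' a spectrum with (near-)zero variance has an undefined R^2 and is
#' returned with `cod = 0` and `valid = FALSE` so it fails the
#' downstream quality filter.
#'
#' @param spectrum Length-B absorbance vector (B >= 3).
#' @param mu B x 2 matrix of absorption coefficients (columns: HbO2,
#'   Hb), from [resample_chromophores()].
#' @return An `unmix_result`: list with raw fitted `c_hbo2`, `c_hb`,
#'   `g_offset`, `cod` and `valid`.
#' @export
unmix_pixel <- function(spectrum, mu) {
  spectrum <- as.numeric(spectrum)
  b <- length(spectrum)
  if (b < 3L) stop("need at least 3 bands to fit two chromophores plus G")
  if (nrow(mu) != b) stop("mu must have one row per band")
  X <- cbind(mu[, 1L], mu[, 2L], 1)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("degenerate design: chromophore spectra are collinear")
  cf <- qr.coef(qx, spectrum)
  fitted <- drop(X %*% cf)
  ss_res <- sum((spectrum - fitted)^2)
  ss_tot <- sum((spectrum - mean(spectrum))^2)
  valid <- ss_tot >= 1e-12
  cod <- if (valid) clamp(1 - ss_res / ss_tot, 0, 1) else 0
  structure(list(c_hbo2 = cf[[1L]], c_hb = cf[[2L]], g_offset = cf[[3L]],
                 cod = cod, valid = valid),
            class = "unmix_result")
}

#' Tissue oxygenation from an unmixing result
#'
#' `c_hbo2 / (c_hbo2 + c_hb)` with negative fitted coefficients
#' clipped at zero before the ratio (the unknown path length cancels).
#' Returns `NA` for invalid fits or a near-zero denominator.
#'
#' @param result An `unmix_result`.
#' @return Oxygenation fraction in [0, 1], or `NA`.
#' @export
oxygenation_of <- function(result) {
  if (!isTRUE(result$valid)) return(NA_real_)
  c1 <- max(result$c_hbo2, 0)
  c2 <- max(result$c_hb, 0)
  if (c1 + c2 < 1e-12) return(NA_real_)
  c1 / (c1 + c2)
}

#' Relative hemoglobin content from an unmixing result
#'
#' `c_hbo2 + c_hb` after the same non-negativity clip; determined only
#' up to the unknown photon path length.
#'
#' @param result An `unmix_result`.
#' @return Relative hemoglobin content in a.u.
#' @export
hb_rel_of <- function(result) {
  if (!isTRUE(result$valid)) return(NA_real_)
  max(result$c_hbo2, 0) + max(result$c_hb, 0)
}

#' Per-pixel parameter maps
#'
#' Container for the per-pixel physiological maps derived from one
#' calibrated cube. All maps share the spatial shape; entries are `NA`
#' exactly where `valid_mask` is `FALSE` (or where an index-specific
#' guard fired).
#'
#' @param oxygenation,hb_rel,cod H x W matrices from the unmixing.
#' @param valid_mask H x W logical matrix.
#' @param superficial,deep Optional H x W index maps.
#' @param c_hbo2,c_hb,g_offset Optional raw (unclipped) coefficient
#'   maps kept for diagnostics.
#' @param camera_ref Camera name.
#' @return Object of class `parameter_maps`.
#' @export
parameter_maps <- function(oxygenation, hb_rel, cod, valid_mask,
                           superficial = NULL, deep = NULL,
                           c_hbo2 = NULL, c_hb = NULL, g_offset = NULL,
                           camera_ref = "") {
  dims <- dim(valid_mask)
  for (m in list(oxygenation, hb_rel, cod, superficial, deep))
    if (!is.null(m) && !all(dim(m) == dims))
      stop("all parameter maps must share the same spatial shape")
  structure(list(oxygenation = oxygenation, hb_rel = hb_rel, cod = cod,
                 superficial = superficial, deep = deep,
                 c_hbo2 = c_hbo2, c_hb = c_hb, g_offset = g_offset,
                 valid_mask = valid_mask, camera_ref = camera_ref),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- dim(x$valid_mask)
  filled <- names(Filter(Negate(is.null),
                         x[c("oxygenation", "hb_rel", "cod",
                             "superficial", "deep")]))
  cat(sprintf("parameter_maps (%s): %d x %d px, %d valid; maps: %s\n",
              x$camera_ref, d[1L], d[2L], sum(x$valid_mask),
              paste(filled, collapse = ", ")))
  invisible(x)
}

#' Unmix every pixel of a calibrated cube
#'
#' Vectorized Beer-Lambert least squares over all pixels (one shared QR
#' factorization of the B x 3 design). Pixels flagged invalid upstream,
#' pixels with zero-variance spectra and pixels whose clipped
#' hemoglobin total is zero are masked out.
#'
#' @param cube A [spectral_cube()] at stage `"l1_reflectance"` (or
#'   already `"absorbance"`).
#' @param library A [chromophore_library()].
#' @param camera A [camera_model()] (hemoglobin-dominant visible range
#'   intended).
#' @param mode Chromophore resampling mode.
#' @return A [parameter_maps()] with `oxygenation`, `hb_rel`, `cod` and
#'   the raw coefficient maps filled.
#' @export
unmix_cube <- function(cube, library, camera, mode = "peak") {
  assert_stage(cube, c("l1_reflectance", "absorbance"))
  if (cube$stage != "absorbance") cube <- absorbance(cube)
  d <- dim(cube$data)
  if (d[3L] < 3L) stop("need at least 3 bands")
  mu <- resample_chromophores(library, camera, mode = mode)
  if (nrow(mu) != d[3L]) stop("camera band count does not match cube")
  X <- cbind(mu[, 1L], mu[, 2L], 1)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("degenerate design: chromophore spectra are collinear")
  A <- flatten_bands(cube$data)                 # B x Npix
  cf <- qr.coef(qx, A)                          # 3 x Npix
  res <- A - X %*% cf
  ss_res <- colSums(res^2)
  abar <- colMeans(A)
  ss_tot <- colSums(A^2) - d[3L] * abar^2
  fit_ok <- ss_tot >= 1e-12
  cod <- ifelse(fit_ok, clamp(1 - ss_res / pmax(ss_tot, 1e-300), 0, 1), 0)

  c1 <- pmax(cf[1L, ], 0)
  c2 <- pmax(cf[2L, ], 0)
  denom <- c1 + c2
  ox_ok <- denom >= 1e-12
  valid <- as.vector(cube$valid) & fit_ok & ox_ok
  shape <- function(v) { v[!valid] <- NA_real_; matrix(v, d[1L], d[2L]) }
  parameter_maps(
    oxygenation = shape(c1 / pmax(denom, 1e-300)),
    hb_rel = shape(denom),
    cod = shape(cod),
    valid_mask = matrix(valid, d[1L], d[2L]),
    c_hbo2 = matrix(cf[1L, ], d[1L], d[2L]),
    c_hb = matrix(cf[2L, ], d[1L], d[2L]),
    g_offset = matrix(cf[3L, ], d[1L], d[2L]),
    camera_ref = cube$camera_ref
  )
}
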