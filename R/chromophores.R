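#' Chromophore absorption library
#'
#' Holds absorption coefficient spectra (cm^-1, whole-blood-equivalent)
#' of fully oxygenated and fully deoxygenated hemoglobin on a common
#' wavelength grid. These two spectra are the columns of the Beer-Lambert
#' design matrix used by the spectral unmixing.
#'
#' @param wavelengths_nm Numeric sampling grid in nm, strictly
#'   increasing, covering at least 450-960 nm.
#' @param mu_hbo2,mu_hb Strictly positive absorption coefficients in
#'   cm^-1 on that grid.
#' @return An object of class `chromophore_library`.
#' @export
chromophore_library <- function(wavelengths_nm, mu_hbo2, mu_hb) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  mu_hbo2 <- as.numeric(mu_hbo2)
  mu_hb <- as.numeric(mu_hb)
  n <- length(wavelengths_nm)
  if (length(mu_hbo2) != n || length(mu_hb) != n)
    stop("wavelength grid and coefficient vectors must have equal length")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (min(wavelengths_nm) > 450 || max(wavelengths_nm) < 960)
    stop("library must cover at least 450-960 nm")
  if (any(mu_hbo2 <= 0) || any(mu_hb <= 0))
    stop("absorption coefficients must be strictly positive")
  structure(list(wavelengths_nm = wavelengths_nm, mu_hbo2 = mu_hbo2,
                 mu_hb = mu_hb),
            class = "chromophore_library")
}

#' Load the packaged hemoglobin absorption table
#'
#' Reads a CSV with columns `wavelength_nm`, `mu_hbo2_cm1`, `mu_hb_cm1`.
#' The default is the table shipped with the package,
#' `hemoglobin_synthetic.csv`: a synthetic, analytically generated
#' stand-in for literature compilations of whole-blood oxy-/deoxy-
#' hemoglobin absorption (see [synthetic_hemoglobin_spectra()]),
#' sampled at 2 nm from 450 to 1000 nm. It reproduces the qualitative
#' landmarks that the oxygenation estimate relies on (the HbO2 double
#' peak at 542/577 nm, the Hb single peak at 556 nm, isosbestic points
#' near 500 and 797 nm, the Hb hump near 760 nm) but is not a verbatim
#' copy of any published table.
#'
#' @param path CSV path; default is the packaged synthetic table.
#' @return A [chromophore_library()].
#' @export
read_chromophores <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hemoglobin_synthetic.csv",
                        package = "oximap", mustWork = TRUE)
  d <- utils::read.csv(path)
  req <- c("wavelength_nm", "mu_hbo2_cm1", "mu_hb_cm1")
  if (!all(req %in% names(d)))
    stop("chromophore CSV must have columns ", paste(req, collapse = ", "))
  chromophore_library(d$wavelength_nm, d$mu_hbo2_cm1, d$mu_hb_cm1)
}

# Knot tables for the analytic spectra: (wavelength nm, mu_a cm^-1),
# whole-blood-equivalent (ca. 150 g hemoglobin per liter). Monotone
# Hermite interpolation between knots guarantees positivity.
.hbo2_knots <- cbind(
  c(440, 450, 460, 470, 480, 490, 498, 506, 514, 522, 530, 535, 542, 548,
    554, 560, 566, 570, 577, 584, 590, 596, 600, 610, 620, 640, 660, 680,
    700, 720, 740, 760, 780, 797, 820, 850, 880, 900, 940, 970, 1000),
  c(560, 336, 180, 148, 140, 125, 112, 118, 135, 150, 210, 245, 285, 260,
    220, 180, 210, 250, 290, 220, 110, 40, 17, 5.5, 3.2, 2.0, 1.7, 1.5,
    1.9, 2.3, 2.7, 3.1, 3.7, 4.3, 5.1, 5.7, 6.1, 6.4, 6.6, 6.5, 6.0)
)
.hb_knots <- cbind(
  c(440, 450, 460, 470, 480, 490, 498, 506, 514, 522, 530, 540, 548, 556,
    562, 570, 576, 584, 590, 596, 600, 610, 620, 640, 660, 680, 700, 720,
    740, 756, 770, 785, 797, 820, 850, 880, 900, 940, 970, 1000),
  c(900, 557, 420, 350, 250, 160, 112, 130, 160, 200, 225, 245, 265, 286,
    280, 245, 205, 160, 120, 95, 79, 50, 35, 25, 17.3, 13.5, 10.5, 9.5,
    9.8, 10.5, 8.5, 6.0, 4.3, 3.9, 3.7, 4.0, 4.1, 3.8, 3.0, 2.3)
)

#' Synthetic hemoglobin absorption spectra
#'
#' Evaluates the analytic oxy-/deoxyhemoglobin absorption model behind
#' the packaged table at arbitrary wavelengths. The model is a monotone
#' cubic Hermite interpolant through hand-placed knots reproducing the
#' canonical shape of whole-blood hemoglobin absorption; it is a
#' synthetic stand-in, not measured data, and is suitable for simulation
#' and for self-consistent unmixing of simulated scenes.
#'
#' @param wavelengths_nm Wavelengths in nm within 440-1000.
#' @return Data frame with columns `wavelength_nm`, `mu_hbo2_cm1`,
#'   `mu_hb_cm1`.
#' @export
synthetic_hemoglobin_spectra <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (any(w < 440) || any(w > 1000))
    stop("synthetic spectra are defined on 440-1000 nm")
  f1 <- stats::splinefun(.hbo2_knots[, 1], .hbo2_knots[, 2], method = "monoH.FC")
  f2 <- stats::splinefun(.hb_knots[, 1], .hb_knots[, 2], method = "monoH.FC")
  data.frame(wavelength_nm = w, mu_hbo2_cm1 = f1(w), mu_hb_cm1 = f2(w))
}

#' Resample a chromophore library onto camera bands
#'
#' @param library A [chromophore_library()].
#' @param camera A [camera_model()]; every band peak must be covered by
#'   the library grid.
#' @param mode `"peak"` (default): linear interpolation of each
#'   coefficient at the band peak. `"fwhm_weighted"`: Gaussian-weighted
#'   average centered at the peak with `sigma = FWHM / 2.355`,
#'   integrated numerically on the library grid over +/- 4 sigma.
#' @return B x 2 matrix with columns `mu_hbo2`, `mu_hb`; strictly
#'   positive.
#' @export
resample_chromophores <- function(library, camera,
                                  mode = c("peak", "fwhm_weighted")) {
  stopifnot(inherits(library, "chromophore_library"),
            inherits(camera, "camera_model"))
  mode <- match.arg(mode)
  w <- library$wavelengths_nm
  peaks <- camera$band_peaks
  if (min(peaks) < min(w) || max(peaks) > max(w))
    stop("camera band range (", min(peaks), "-", max(peaks),
         " nm) not covered by chromophore library (", min(w), "-",
         max(w), " nm)")
  if (mode == "peak") {
    out <- cbind(
      mu_hbo2 = stats::approx(w, library$mu_hbo2, xout = peaks)$y,
      mu_hb = stats::approx(w, library$mu_hb, xout = peaks)$y
    )
  } else {
    b <- length(peaks)
    out <- matrix(NA_real_, b, 2, dimnames = list(NULL, c("mu_hbo2", "mu_hb")))
    for (i in seq_len(b)) {
      sigma <- camera$band_fwhm[i] / 2.355
      sel <- which(w >= peaks[i] - 4 * sigma & w <= peaks[i] + 4 * sigma)
      if (length(sel) < 2L) {
        # band narrower than the grid spacing: fall back to the peak value
        out[i, ] <- c(stats::approx(w, library$mu_hbo2, xout = peaks[i])$y,
                      stats::approx(w, library$mu_hb, xout = peaks[i])$y)
        next
      }
      wt <- stats::dnorm(w[sel], mean = peaks[i], sd = sigma)
      wt <- wt / sum(wt)
      out[i, ] <- c(sum(wt * library$mu_hbo2[sel]),
                    sum(wt * library$mu_hb[sel]))
    }
  }
  out
}
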