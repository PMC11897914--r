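test_that("shipped descriptors load with the documented geometry", {
  vis <- fx_vis()
  expect_equal(length(vis$band_peaks), 16L)
  expect_equal(vis$mosaic_shape, c(4L, 4L))
  expect_equal(range(vis$band_peaks), c(460, 596))
  nir <- fx_nir()
  expect_equal(length(nir$band_peaks), 25L)
  expect_equal(nir$mosaic_shape, c(5L, 5L))
  expect_equal(range(nir$band_peaks), c(659, 947))
  # default tile layout is a bijection onto tile positions
  for (cam in list(vis, nir)) {
    key <- cam$band_to_tile[, 1] * cam$mosaic_shape[2] + cam$band_to_tile[, 2]
    expect_setequal(key, seq_len(prod(cam$mosaic_shape)) - 1L)
  }
})

test_that("camera_model rejects inconsistent descriptors", {
  expect_error(camera_model("X", c(500, 510), c(10, 10, 10), c(1, 2), c(8, 8)),
               "same length")
  expect_error(camera_model("X", c(510, 500), c(10, 10), c(1, 2), c(8, 8)),
               "increasing")
  expect_error(camera_model("X", c(500, 510, 520), c(10, 10, 10), c(1, 2),
                            c(8, 8)),
               "mosaic")
  expect_error(camera_model("X", c(500, 510), c(10, 10), c(1, 2), c(8, 8),
                            band_to_tile = rbind(c(0, 0), c(0, 0))),
               "bijection")
  expect_error(camera_model("X", c(500, 510), c(10, 10), c(1, 2), c(8, 8),
                            correction_matrix = diag(3)),
               "2 x 2")
})

test_that("band range selection uses inclusive peak membership", {
  vis <- fx_vis()
  expect_equal(vis$band_peaks[bands_in_range(vis, 530, 580)],
               c(532, 546, 550, 564, 570))
  expect_equal(vis$band_peaks[bands_in_range(vis, 496, 504)], c(496, 504))
  nir <- fx_nir()
  expect_length(bands_in_range(nir, 826, 928), 10L)
  expect_length(bands_in_range(nir, 668, 739), 6L)
  expect_length(bands_in_range(vis, 1000, 1100), 0L)
  # full range returns every band
  expect_equal(bands_in_range(vis, min(vis$band_peaks), max(vis$band_peaks)),
               seq_len(16L))
  expect_error(bands_in_range(vis, 600, 500))
})

test_that("nearest band resolves the RGB channel wavelengths", {
  vis <- fx_vis()
  expect_equal(vis$band_peaks[nearest_band(vis, 597)], 596)
  expect_equal(vis$band_peaks[nearest_band(vis, 551)], 550)
  expect_equal(vis$band_peaks[nearest_band(vis, 460)], 460)
  # every band peak maps to itself
  for (i in seq_along(vis$band_peaks))
    expect_equal(nearest_band(vis, vis$band_peaks[i]), i)
  # ties break toward the shorter wavelength
  cam <- tiny_camera(peaks = c(500, 510, 520, 530))
  expect_equal(nearest_band(cam, 505), 1L)
  expect_equal(nearest_band(cam, 515), 2L)
})

test_that("chromophore resampling reproduces table values at knots", {
  vis <- fx_vis()
  lib <- fx_lib()
  # library sampled exactly at the band peaks: peak mode is verbatim
  at_peaks <- chromophore_library(
    c(440, vis$band_peaks, 960, 1000),
    c(5, seq_along(vis$band_peaks) + 10, 5, 5),
    c(7, rev(seq_along(vis$band_peaks)) + 20, 7, 7))
  mu <- resample_chromophores(at_peaks, vis, mode = "peak")
  expect_equal(unname(mu[, 1]), seq_len(16) + 10)
  expect_equal(unname(mu[, 2]), rev(seq_len(16)) + 20)
  expect_true(all(resample_chromophores(lib, vis) > 0))
  expect_equal(nrow(resample_chromophores(lib, fx_nir())), 25L)
})

test_that("FWHM-weighted resampling matches the quadrature oracle", {
  vis <- fx_vis()
  # constant library: identical under both modes
  w <- seq(440, 1000, by = 2)
  flat <- chromophore_library(w, rep(3, length(w)), rep(5, length(w)))
  expect_equal(resample_chromophores(flat, vis, "peak"),
               resample_chromophores(flat, vis, "fwhm_weighted"))
  # linear-in-wavelength library: Gaussian weighting preserves the
  # center value (independent quadrature oracle on the same grid)
  lin <- chromophore_library(w, 1 + 0.01 * (w - 440), 2 + 0.005 * (w - 440))
  got <- resample_chromophores(lin, vis, "fwhm_weighted")
  oracle <- t(vapply(seq_along(vis$band_peaks), function(i) {
    s <- vis$band_fwhm[i] / 2.355
    sel <- w >= vis$band_peaks[i] - 4 * s & w <= vis$band_peaks[i] + 4 * s
    wt <- dnorm(w[sel], vis$band_peaks[i], s)
    c(sum(wt * lin$mu_hbo2[sel]) / sum(wt), sum(wt * lin$mu_hb[sel]) / sum(wt))
  }, numeric(2)))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  peak <- resample_chromophores(lin, vis, "peak")
  expect_equal(got, peak, tolerance = 2e-3)
  # coverage error for a camera extending past the library grid
  narrow <- chromophore_library(seq(450, 960, 2), rep(1, 256), rep(1, 256))
  beyond <- tiny_camera(peaks = c(900, 930, 970, 990))
  expect_error(resample_chromophores(narrow, beyond), "not covered")
})
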