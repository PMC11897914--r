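test_that("dark subtraction clips at zero and checks shapes", {
  raw <- matrix(c(100, 40, 10, 0), 2)
  dark <- matrix(c(40, 40, 40, 0), 2)
  expect_equal(dark_subtract(raw, dark), matrix(c(60, 0, 0, 0), 2))
  expect_equal(dark_subtract(raw, raw), matrix(0, 2, 2))
  expect_error(dark_subtract(raw, matrix(0, 3, 2)), "shape")
})

test_that("demosaicing reproduces constants and exact sample sites", {
  cam <- tiny_camera(sensor = c(12, 12))
  const <- matrix(4.2, 12, 12)
  cube <- demosaic(const, cam)
  expect_equal(cube$stage, "counts")
  expect_equal(dim(cube$data), c(12L, 12L, 4L))
  expect_lt(max(abs(cube$data - 4.2)), 1e-6)
  # bilinear ramp: every band plane matches the ramp at its own
  # sample sites exactly (Lanczos weight 1 at integer sample offsets)
  ramp <- outer(seq_len(12), seq_len(12), function(y, x) 2 * y + 3 * x)
  rc <- demosaic(ramp, cam)
  for (b in 1:4) {
    tr <- cam$band_to_tile[b, 1]; tc <- cam$band_to_tile[b, 2]
    rows <- seq(tr + 1, 12, by = 2); cols <- seq(tc + 1, 12, by = 2)
    expect_equal(rc$data[rows, cols, b], ramp[rows, cols], tolerance = 1e-12)
  }
  # odd frame size is cropped to the tile multiple
  cube2 <- demosaic(matrix(1, 13, 15), cam)
  expect_equal(dim(cube2$data)[1:2], c(12L, 14L))
})

test_that("native-resolution VIS frame demosaics to 16 full planes", {
  vis <- fx_vis()
  frame <- matrix(7, 1088, 2048)
  cube <- demosaic(frame, vis)
  expect_equal(dim(cube$data), c(1088L, 2048L, 16L))
  expect_lt(max(abs(cube$data - 7)), 1e-6)
})

test_that("bilateral denoising preserves constants and edges, reduces noise", {
  cam <- tiny_camera(sensor = c(32, 32))
  const <- cube_from_planes(rep(list(matrix(5, 32, 32)), 4), "counts",
                            cam$band_peaks)
  expect_equal(denoise_bands(const)$data, const$data)
  # step edge much larger than sigma_range keeps its location
  step <- matrix(rep(c(0, 100), each = 16), 32, 32, byrow = TRUE)
  sc <- cube_from_planes(list(step, step, step, step), "counts",
                         cam$band_peaks)
  den <- denoise_bands(sc, sigma_spatial = 2, sigma_range = 5)$data[, , 1]
  grad_in <- apply(abs(diff(t(step))), 1, max)
  grad_out <- apply(abs(diff(t(den))), 1, max)
  expect_equal(which.max(grad_out), which.max(grad_in))
  # Gaussian noise on a smooth plane: variance strictly reduced
  set.seed(11)
  smooth <- outer(seq_len(32), seq_len(32), function(y, x) y + x)
  noisy <- smooth + matrix(rnorm(32 * 32, sd = 2), 32, 32)
  nc <- cube_from_planes(rep(list(noisy), 4), "counts", cam$band_peaks)
  out <- denoise_bands(nc, sigma_spatial = 2, sigma_range = 6)$data[, , 1]
  expect_lt(var(as.vector(out - smooth)), var(as.vector(noisy - smooth)))
})

test_that("spectral correction acts per pixel in band space", {
  cam <- tiny_camera()
  set.seed(2)
  planes <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
  cube <- cube_from_planes(planes, "counts", cam$band_peaks)
  ident <- apply_correction(cube, diag(4))
  expect_equal(ident$data, cube$data)
  expect_equal(ident$stage, "irradiance")
  P <- diag(4)[c(2, 1, 4, 3), ]
  perm <- apply_correction(cube, P)
  expect_equal(perm$data[, , 1], cube$data[, , 2])
  expect_equal(perm$data[, , 4], cube$data[, , 3])
  expect_error(apply_correction(cube, diag(3)), "4 x 4")
  expect_error(apply_correction(ident, diag(4)), "stage")
})

test_that("simulated sensor imperfection is undone by the correction matrix", {
  C <- diag(16)
  C[cbind(1:15, 2:16)] <- -0.05   # invertible band-mixing correction
  vis_c <- camera_model("VISC", fx_vis()$band_peaks, fx_vis()$band_fwhm,
                        c(4, 4), c(64, 64), correction_matrix = C)
  rt <- fx_roundtrip()
  b_imp <- render_raw(rt$refl, vis_c, illumination_preset("vis_led"),
                      noise_off(), seed = 3, imperfect = TRUE)
  cal <- calibrate(b_imp, config = calib_config(denoise = FALSE))
  truth <- l1_normalize(rt$refl)$data
  expect_lt(max(abs(cal$data - truth)[9:56, 9:56, ]), 2e-2)
})

test_that("illumination estimation averages bands then min-max normalizes", {
  planes <- list(matrix(10, 8, 8), matrix(20, 8, 8), matrix(30, 8, 8),
                 matrix(20, 8, 8))
  cam4 <- tiny_camera(peaks = c(500, 520, 540, 560))
  white <- cube_from_planes(planes, "irradiance", cam4$band_peaks)
  ill <- estimate_illumination(white)
  expect_equal(ill$relative_power, c(0, 0.5, 1, 0.5))
  expect_equal(ill$power, c(10, 20, 30, 20) / 30)
  # spatially varying but band-proportional white gives the same result
  g <- outer(seq_len(8), seq_len(8), function(y, x) 1 + 0.1 * y)
  white2 <- cube_from_planes(lapply(c(10, 20, 30, 20), function(v) v * g),
                             "irradiance", cam4$band_peaks)
  expect_equal(estimate_illumination(white2)$relative_power,
               c(0, 0.5, 1, 0.5))
  dark <- cube_from_planes(rep(list(matrix(0, 8, 8)), 4), "irradiance",
                           cam4$band_peaks)
  expect_error(estimate_illumination(dark), "degenerate")
})

test_that("white balancing divides by the source spectrum with a guard", {
  cam <- tiny_camera(peaks = c(500, 520, 540, 560))
  ill <- illumination_spectrum(c(500, 520, 540, 560), c(0.5, 1, 0.25, 1e-5))
  planes <- lapply(c(0.5, 1, 0.25, 1e-5), function(v) matrix(v, 8, 8))
  cube <- cube_from_planes(planes, "irradiance", cam$band_peaks)
  refl <- to_reflectance(cube, ill)
  expect_equal(refl$stage, "reflectance")
  # cube equal to the illumination spectrum: reflectance 1 on unguarded bands
  expect_equal(refl$data[, , 1:3], array(1, c(8, 8, 3)))
  expect_equal(refl$band_flags, c(FALSE, FALSE, FALSE, TRUE))
  # halving illumination at one band doubles reflectance there
  ill2 <- illumination_spectrum(c(500, 520, 540, 560), c(0.25, 1, 0.25, 1e-5))
  expect_equal(to_reflectance(cube, ill2)$data[, , 1],
               2 * refl$data[, , 1])
})

test_that("L1 normalization is exact, scale-free and flags zero pixels", {
  cam <- tiny_camera(peaks = c(500, 520, 540, 560))
  planes <- list(matrix(1, 4, 4), matrix(3, 4, 4), matrix(0, 4, 4),
                 matrix(0, 4, 4))
  cube <- cube_from_planes(planes, "reflectance", cam$band_peaks)
  l1 <- l1_normalize(cube)
  expect_equal(l1$stage, "l1_reflectance")
  expect_equal(l1$data[1, 1, ], c(0.25, 0.75, 0, 0))
  # per-pixel scaling leaves the result unchanged
  scaled <- cube
  scaled$data <- cube$data * 17.3
  expect_equal(l1_normalize(scaled)$data, l1$data, tolerance = 1e-12)
  # all-zero pixel flagged invalid, output zeros
  zplanes <- lapply(planes, function(p) { p[2, 2] <- 0; p })
  zc <- cube_from_planes(zplanes, "reflectance", cam$band_peaks)
  zl <- l1_normalize(zc)
  expect_false(zl$valid[2, 2])
  expect_equal(zl$data[2, 2, ], rep(0, 4))
  expect_true(all(abs(apply(abs(zl$data), c(1, 2), sum)[zl$valid] - 1) < 1e-9))
})

test_that("full calibration recovers the ground-truth L1 reflectance", {
  rt <- fx_roundtrip()
  expect_equal(rt$cal$stage, "l1_reflectance")
  s <- apply(abs(rt$cal$data), c(1, 2), sum)
  expect_lt(max(abs(s[rt$cal$valid] - 1)), 1e-9)
  truth <- l1_normalize(rt$refl)$data
  # interior comparison: reflect-padding extrapolation at the frame
  # border is the documented weak spot of the demosaicer
  expect_lt(max(abs(rt$cal$data - truth)[9:56, 9:56, ]), 1e-2)
  # missing white reference is an explicit error
  broken <- rt$bundle
  broken$white_raw_frame <- NULL
  expect_error(calibrate(broken), "white-reference")
})

test_that("multi-frame bundles are averaged after dark subtraction", {
  rt <- fx_roundtrip()
  b <- render_raw(rt$refl, fx_vis(), illumination_preset("vis_led"),
                  noise_params(), seed = 31, n_frames = 3)
  mean_cal <- calibrate(b)
  one_cal <- calibrate(b, config = calib_config(frame = 2))
  expect_false(identical(mean_cal$data, one_cal$data))
  expect_error(calibrate(b, config = calib_config(frame = 9)), "out of range")
  # temporal averaging brings the noisy cube closer to the clean one
  clean <- rt$cal$data
  b1 <- b; b1$raw_frames <- b$raw_frames[1]
  d_mean <- mean(abs(mean_cal$data - clean))
  d_one <- mean(abs(calibrate(b1)$data - clean))
  expect_lt(d_mean, d_one)
})

test_that("stage ordering is enforced across the chain", {
  cam <- tiny_camera(peaks = c(500, 520, 540, 560))
  planes <- rep(list(matrix(1, 4, 4)), 4)
  counts <- cube_from_planes(planes, "counts", cam$band_peaks)
  refl <- cube_from_planes(planes, "reflectance", cam$band_peaks)
  ill <- illumination_spectrum(c(500, 560), c(1, 1))
  expect_error(l1_normalize(counts), "stage")
  expect_error(to_reflectance(refl, ill), "stage")
  expect_error(estimate_illumination(counts), "stage")
  expect_error(absorbance(counts), "stage")
  expect_error(denoise_bands(l1_normalize(refl)), "stage")
})
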