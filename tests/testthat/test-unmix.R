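test_that("absorbance is -log with a guarded floor", {
  cam <- tiny_camera(peaks = c(500, 520, 540, 560))
  planes <- list(matrix(1, 4, 4), matrix(exp(-1), 4, 4),
                 matrix(0.5, 4, 4), matrix(0, 4, 4))
  cube <- cube_from_planes(planes, "reflectance", cam$band_peaks)
  a <- absorbance(cube)
  expect_equal(a$stage, "absorbance")
  expect_equal(a$data[1, 1, 1], 0)
  expect_equal(a$data[1, 1, 2], 1)
  expect_equal(a$data[1, 1, 4], -log(1e-6))
  expect_true(all(a$floored))
  # monotone: smaller reflectance, larger absorbance
  expect_true(all(diff(a$data[1, 1, c(1, 3, 2)]) > 0))
})

test_that("single-pixel unmixing matches the normal-equations oracle", {
  lib <- fx_lib(); vis <- fx_vis()
  mu <- resample_chromophores(lib, vis)
  X <- cbind(mu[, 1], mu[, 2], 1)
  set.seed(21)
  for (i in 1:200) {
    cf <- c(runif(1, 0, 0.01), runif(1, 0, 0.01), runif(1, 0, 0.5))
    y <- drop(X %*% cf) + rnorm(16, sd = 0.01)
    got <- unmix_pixel(y, mu)
    oracle <- drop(solve(crossprod(X), crossprod(X, y)))
    expect_equal(c(got$c_hbo2, got$c_hb, got$g_offset), oracle,
                 tolerance = 1e-9)
    fitted <- drop(X %*% oracle)
    r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
    expect_equal(got$cod, r2, tolerance = 1e-9)
  }
})

test_that("analytic unmixing cases behave as constructed", {
  lib <- fx_lib(); vis <- fx_vis()
  mu <- resample_chromophores(lib, vis)
  # exact linear combination: coefficients and COD recovered exactly
  y <- 0.8 * mu[, 1] + 0.2 * mu[, 2] + 0.1
  r <- unmix_pixel(y, mu)
  expect_equal(c(r$c_hbo2, r$c_hb, r$g_offset), c(0.8, 0.2, 0.1),
               tolerance = 1e-9)
  expect_equal(r$cod, 1, tolerance = 1e-9)
  # pure oxyhemoglobin: oxygenation 1
  p <- unmix_pixel(0.5 * mu[, 1], mu)
  expect_equal(p$c_hb, 0, tolerance = 1e-9)
  expect_equal(oxygenation_of(p), 1)
  # flat spectrum: intercept-only fit, invalid
  f <- unmix_pixel(rep(0.3, 16), mu)
  expect_false(f$valid)
  expect_equal(f$cod, 0)
  expect_equal(f$g_offset, 0.3, tolerance = 1e-9)
  expect_true(is.na(oxygenation_of(f)))
  # collinear design is a hard error
  mu_bad <- cbind(mu[, 1], 2 * mu[, 1])
  expect_error(unmix_pixel(y, mu_bad), "degenerate design")
  expect_error(unmix_pixel(y[1:2], mu[1:2, ]), "at least 3 bands")
})

test_that("oxygenation and Hbrel reporting clips negatives", {
  mk <- function(c1, c2) structure(list(c_hbo2 = c1, c_hb = c2,
                                        g_offset = 0, cod = 1, valid = TRUE),
                                   class = "unmix_result")
  expect_equal(oxygenation_of(mk(0.3, 0.3)), 0.5)
  expect_equal(oxygenation_of(mk(0.4, 0)), 1)
  expect_equal(oxygenation_of(mk(-0.1, 0.3)), 0)
  expect_true(is.na(oxygenation_of(mk(-0.1, -0.2))))
  expect_equal(hb_rel_of(mk(0.8, 0.2)), 1)
  expect_equal(hb_rel_of(mk(-0.5, 0.2)), 0.2)
})

test_that("Hbrel is linear in the hemoglobin part of absorbance", {
  lib <- fx_lib(); vis <- fx_vis()
  mu <- resample_chromophores(lib, vis)
  y1 <- 0.4 * mu[, 1] + 0.1 * mu[, 2] + 0.2
  y2 <- 2 * (0.4 * mu[, 1] + 0.1 * mu[, 2]) + 0.2
  expect_equal(hb_rel_of(unmix_pixel(y2, mu)),
               2 * hb_rel_of(unmix_pixel(y1, mu)), tolerance = 1e-9)
})

test_that("log base only rescales coefficients, not derived parameters", {
  lib <- fx_lib(); vis <- fx_vis()
  mu <- resample_chromophores(lib, vis)
  set.seed(5)
  y <- 0.6 * mu[, 1] + 0.3 * mu[, 2] + 0.2 + rnorm(16, sd = 0.02)
  nat <- unmix_pixel(y, mu)
  dec <- unmix_pixel(y / log(10), mu)  # base-10 absorbance
  expect_equal(oxygenation_of(dec), oxygenation_of(nat), tolerance = 1e-9)
  expect_equal(dec$cod, nat$cod, tolerance = 1e-9)
  expect_equal(hb_rel_of(dec) * log(10), hb_rel_of(nat), tolerance = 1e-9)
})

test_that("cube unmixing recovers the noise-free phantom exactly", {
  lib <- fx_lib(); vis <- fx_vis()
  scene <- make_phantom(48, 48, "cabg", "pre", seed = 13)
  refl <- forward_reflectance(scene, lib, vis)
  maps <- unmix_cube(l1_normalize(refl), lib, vis)
  ns <- !scene$specular_mask
  expect_lt(max(abs(maps$oxygenation - scene$oxygenation)[ns], na.rm = TRUE),
            1e-6)
  expect_lt(max(abs(maps$hb_rel - (scene$c_hbo2 + scene$c_hb))[ns],
                na.rm = TRUE), 1e-6)
  expect_equal(min(maps$cod[ns], na.rm = TRUE), 1, tolerance = 1e-9)
  # specular pixels: flat high reflectance, invalid / excluded
  expect_true(any(scene$specular_mask))
  expect_false(any(maps$valid_mask[scene$specular_mask]))
  # G is recovered when unmixing plain (non-L1) absorbance
  maps_g <- unmix_cube(absorbance(refl), lib, vis)
  expect_lt(max(abs(maps_g$g_offset - scene$g_offset)[ns]), 1e-6)
})

test_that("cube unmixing handles degenerate inputs and bounds COD", {
  cam <- tiny_camera(peaks = c(500, 520, 540, 560))
  lib <- tiny_library()
  # all-invalid cube: everything masked, no error
  planes <- rep(list(matrix(0, 4, 4)), 4)
  cube <- l1_normalize(cube_from_planes(planes, "reflectance",
                                        cam$band_peaks))
  maps <- unmix_cube(cube, lib, cam)
  expect_false(any(maps$valid_mask))
  expect_true(all(is.na(maps$oxygenation)))
  # noisy random spectra: COD always within [0, 1] on valid pixels
  set.seed(31)
  rp <- lapply(1:4, function(i) matrix(runif(64, 0.1, 1), 8, 8))
  rcube <- l1_normalize(cube_from_planes(rp, "reflectance", cam$band_peaks))
  rmaps <- unmix_cube(rcube, lib, cam)
  cods <- rmaps$cod[rmaps$valid_mask]
  expect_true(all(cods >= 0 & cods <= 1))
})

test_that("derived parameters are invariant to per-pixel reflectance scale", {
  rt <- fx_roundtrip()
  lib <- fx_lib(); vis <- fx_vis()
  cube <- rt$cal
  # multiply each pixel's spectrum by its own positive factor
  d <- dim(cube$data)
  set.seed(41)
  k <- matrix(runif(d[1] * d[2], 0.5, 2), d[1], d[2])
  scaled <- cube
  scaled$data <- sweep(cube$data, c(1, 2), k, "*")
  scaled$stage <- "reflectance"
  scaled <- l1_normalize(scaled)
  m1 <- unmix_cube(cube, lib, vis)
  m2 <- unmix_cube(scaled, lib, vis)
  expect_equal(m2$oxygenation, m1$oxygenation, tolerance = 1e-9)
  expect_equal(m2$cod, m1$cod, tolerance = 1e-9)
  expect_equal(superficial_index(scaled, vis), superficial_index(cube, vis),
               tolerance = 1e-9)
})
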