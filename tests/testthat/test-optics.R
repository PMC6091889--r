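test_that("diffraction PSF is normalized with an Airy first zero", {
  psf <- diffraction_limited_psf(550, 7.75)
  expect_equal(sum(psf$grid), 1, tolerance = 1e-6)
  expect_true(all(psf$grid >= 0))
  n <- nrow(psf$grid); mid <- (n + 1) / 2
  expect_equal(which.max(psf$grid[mid, ]), mid)
  # first zero along the central row, quadratic-refined (oracle: 1.22 l/D)
  row <- psf$grid[mid, ]
  ix <- (seq_len(n) - mid) * psf$pixel_scale_arcmin
  sel <- which(ix > 0.15 & ix < 0.45)
  i0 <- sel[which.min(row[sel])]
  co <- coef(lm(row[(i0 - 1):(i0 + 1)] ~ poly(ix[(i0 - 1):(i0 + 1)], 2,
                                              raw = TRUE)))
  zero <- -co[2] / (2 * co[3])
  expect_equal(unname(zero), 1.22 * core_fwhm_lambda_over_d(550, 7.75),
               tolerance = 0.02)
  expect_error(diffraction_limited_psf(550, 8, pixel_scale_arcmin = 0.2),
               "undersampled")
})

measure_fwhm <- function(psf) {
  n <- nrow(psf$grid); mid <- (n + 1) / 2
  row <- psf$grid[mid, ]
  hm <- max(row) / 2
  i <- mid + which(row[mid:n] < hm)[1] - 1
  x1 <- (i - 1 - mid) * psf$pixel_scale_arcmin
  x2 <- (i - mid) * psf$pixel_scale_arcmin
  2 * (x1 + (hm - row[i - 1]) / (row[i] - row[i - 1]) * (x2 - x1))
}

test_that("PSF width scales inversely with pupil and matches conventions", {
  expect_equal(round(core_fwhm_lambda_over_d(550, 7.75), 2), 0.24)
  expect_equal(round(core_fwhm_lambda_over_d(550, 3.875), 2), 0.49)
  p1 <- diffraction_limited_psf(550, 7.75)
  p2 <- diffraction_limited_psf(550, 3.875, pixel_scale_arcmin = 0.06,
                                side_px = 513)
  f1 <- measure_fwhm(p1); f2 <- measure_fwhm(p2)
  expect_equal(f2 / f1, 2, tolerance = 0.02)
  # numeric half-max width of the Airy core is 1.029 lambda/D
  expect_equal(f1, 1.029 * core_fwhm_lambda_over_d(550, 7.75),
               tolerance = 0.02)
})

test_that("Zernike PSF reduces to Airy, respects symmetry and Strehl", {
  airy <- diffraction_limited_psf(550, 3, pixel_scale_arcmin = 0.05,
                                  side_px = 257)
  z0 <- psf_from_zernike(numeric(15), pupil_mm = 3,
                         pixel_scale_arcmin = 0.05, side_px = 257)
  expect_lt(sqrt(mean((z0$grid - airy$grid)^2)), 1e-6)
  # defocus only: rotationally symmetric
  cz <- numeric(15); cz[5] <- 0.05
  zd <- psf_from_zernike(cz, pupil_mm = 3, pixel_scale_arcmin = 0.05,
                         side_px = 257)
  expect_equal(sum(zd$grid), 1, tolerance = 1e-6)
  asym <- max(abs(zd$grid - t(zd$grid))) / max(zd$grid)
  expect_lt(asym, 0.01)
  # any aberration: Strehl <= 1
  za <- typical_aberrations()
  zt <- psf_from_zernike(za$osa_coeffs_microns, pupil_mm = 3,
                         pixel_scale_arcmin = 0.05, side_px = 257)
  expect_lte(max(zt$grid), max(airy$grid) * (1 + 1e-9))
})

test_that("optical blur is linear, flux conserving, with delta response", {
  psf <- diffraction_limited_psf(550, 8, pixel_scale_arcmin = 0.05,
                                 side_px = 65)
  img <- matrix(0, 101, 101)
  img[51, 51] <- 1
  out <- apply_optics(img, psf, 0.05)
  # impulse response equals the PSF
  expect_equal(out[19:83, 19:83], psf$grid, tolerance = 1e-9)
  # flux conservation for an interior source
  disk <- matrix(0, 101, 101)
  disk[40:60, 40:60] <- 2.5
  blurred <- apply_optics(disk, psf, 0.05)
  expect_equal(sum(blurred) / sum(disk), 1, tolerance = 1e-6)
  # central value of a patch wider than the PSF support is unchanged
  wide <- matrix(0, 161, 161)
  wide[41:121, 41:121] <- 2.5
  expect_equal(apply_optics(wide, psf, 0.05)[81, 81], 2.5,
               tolerance = 1e-6)
  # linearity
  i2 <- matrix(runif(101 * 101), 101, 101)
  lhs <- apply_optics(2 * disk + 3 * i2, psf, 0.05)
  rhs <- 2 * apply_optics(disk, psf, 0.05) + 3 * apply_optics(i2, psf, 0.05)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(apply_optics(img, psf, 0.1), "pixel scales")
})
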