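# Point-spread functions by the pupil-function method and retinal-image
# formation by convolution.
#
# The PSF is |FT(pupil)|^2 on an angular grid.  For a PSF grid of side N and
# angular sample dtheta (radians), the conjugate pupil-plane sample spacing
# is du = lambda / (N * dtheta); the pupil of diameter D then has radius
# (D/2)/du samples.  The aperture edge is anti-aliased with a one-sample
# linear ramp so that radial metrics (first Airy zero, FWHM) are accurate at
# moderate grid sizes.

ARCMIN_PER_RAD <- 180 / pi * 60

.pupil_psf <- function(phase_fun, wavelength_nm, pupil_mm,
                       pixel_scale_arcmin, side_px) {
  if (side_px %% 2 != 1) stop("PSF side_px must be odd")
  lambda_m <- wavelength_nm * 1e-9
  d_m <- pupil_mm * 1e-3
  dtheta <- pixel_scale_arcmin / ARCMIN_PER_RAD
  nyq <- (lambda_m / d_m) * ARCMIN_PER_RAD / 4
  if (pixel_scale_arcmin > nyq * (1 + 1e-9)) {
    stop(sprintf(paste0("PSF undersampled: pixel scale %.4g arcmin exceeds ",
                        "lambda/D/4 = %.4g arcmin"),
                 pixel_scale_arcmin, nyq))
  }
  du <- lambda_m / (side_px * dtheta)
  r_samp <- (d_m / 2) / du
  if (r_samp > side_px / 2) {
    stop("PSF grid too small for the pupil at this pixel scale")
  }
  ix <- seq_len(side_px) - (side_px + 1) / 2
  rho <- sqrt(outer(ix^2, ix^2, `+`)) / r_samp       # normalized pupil radius
  amp <- pmin(pmax((1 - rho) * r_samp + 0.5, 0), 1)  # anti-aliased edge
  pupil <- amp
  if (!is.null(phase_fun)) {
    theta <- atan2(matrix(ix, side_px, side_px, byrow = TRUE),
                   matrix(ix, side_px, side_px))
    ph <- phase_fun(pmin(rho, 1), theta)
    pupil <- amp * exp(1i * ph)
  }
  field <- stats::fft(.ifftshift(pupil))
  psf <- Mod(.fftshift(field))^2
  psf / sum(psf)
}

# fftshift: move DC (index 1) to the grid center, floor(n/2)+1.
.fftshift <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((n1 - s1 + 1):n1, 1:(n1 - s1)), c((n2 - s2 + 1):n2, 1:(n2 - s2))]
}

# ifftshift: inverse of .fftshift (move the grid center to index 1).
.ifftshift <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

.new_psf <- function(grid, pixel_scale_arcmin, wavelength_nm, pupil_mm) {
  structure(list(grid = grid, pixel_scale_arcmin = pixel_scale_arcmin,
                 wavelength_nm = wavelength_nm, pupil_mm = pupil_mm),
            class = "psf")
}

#' Diffraction-limited point-spread function
#'
#' Airy pattern of an unaberrated circular pupil, computed by Fourier
#' transform of the pupil function and normalized to unit volume.
#'
#' @param wavelength_nm Wavelength in nm (default 550).
#' @param pupil_mm Pupil diameter in mm (default 8, the model's corrected
#'   condition).
#' @param pixel_scale_arcmin Angular sampling of the PSF grid; must satisfy
#'   the Nyquist margin `<= (lambda/D)/4`.
#' @param side_px Odd grid side length.
#' @return Object of class `"psf"`: list with `grid` (side_px x side_px,
#'   sums to 1), `pixel_scale_arcmin`, `wavelength_nm`, `pupil_mm`.
#' @export
diffraction_limited_psf <- function(wavelength_nm = 550, pupil_mm = 8,
                                    pixel_scale_arcmin = 0.03,
                                    side_px = 513) {
  stopifnot(wavelength_nm > 0, pupil_mm > 0, pixel_scale_arcmin > 0)
  g <- .pupil_psf(NULL, wavelength_nm, pupil_mm, pixel_scale_arcmin, side_px)
  .new_psf(g, pixel_scale_arcmin, wavelength_nm, pupil_mm)
}

#' Width of the diffraction core, lambda/D convention
#'
#' Returns `lambda / D` converted from radians to arcmin — the conventional
#' single-number width of the diffraction-limited PSF core.  (The half-max
#' width of the Airy core measured on the numeric grid is the slightly
#' larger `1.029 lambda/D`; both conventions are exposed, this function
#' implements the former.)
#'
#' @param wavelength_nm Wavelength in nm.
#' @param pupil_mm Pupil diameter in mm.
#' @return Core width in arcmin.
#' @export
#' @examples
#' core_fwhm_lambda_over_d(550, 7.75)  # 0.24 arcmin
core_fwhm_lambda_over_d <- function(wavelength_nm, pupil_mm) {
  if (wavelength_nm <= 0 || pupil_mm <= 0) {
    stop("core_fwhm_lambda_over_d(): arguments must be positive")
  }
  (wavelength_nm * 1e-9) / (pupil_mm * 1e-3) * ARCMIN_PER_RAD
}

# OSA/ANSI single index j -> (n, m)
.osa_nm <- function(j) {
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  c(n = n, m = m)
}

# Radial Zernike polynomial R_n^|m|(rho)
.zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  s_max <- (n - m) / 2
  out <- 0
  for (s in 0:s_max) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

# Normalized Zernike polynomial, OSA/ANSI convention.
.zernike <- function(j, rho, theta) {
  nm <- .osa_nm(j)
  n <- nm["n"]; m <- nm["m"]
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  r <- .zernike_radial(n, m, rho)
  if (m > 0) norm * r * cos(m * theta)
  else if (m < 0) norm * r * sin(-m * theta)
  else norm * r
}

#' Point-spread function from Zernike coefficients
#'
#' Builds the generalized pupil function with phase
#' `2 pi / lambda * sum_j c_j Z_j(rho, theta)` (coefficients in microns,
#' OSA/ANSI single indexing with piston first) and returns the normalized
#' `|FT(pupil)|^2`.  Piston, tip and tilt (j = 0, 1, 2) only displace or
#' offset the PSF and are ignored.
#'
#' @param coeffs Numeric vector of OSA-ordered Zernike coefficients in
#'   microns (element 1 is j = 0), defined over `pupil_mm`.
#' @param pupil_mm Pupil diameter the coefficients refer to.
#' @param wavelength_nm Wavelength in nm.
#' @param pixel_scale_arcmin,side_px PSF grid parameters as in
#'   [diffraction_limited_psf()].
#' @return A `"psf"` object.
#' @export
psf_from_zernike <- function(coeffs, pupil_mm = 3, wavelength_nm = 550,
                             pixel_scale_arcmin = 0.05, side_px = 257) {
  stopifnot(is.numeric(coeffs), all(is.finite(coeffs)))
  cz <- coeffs
  cz[seq_len(min(3, length(cz)))] <- 0  # piston/tip/tilt
  lambda_um <- wavelength_nm * 1e-3
  phase_fun <- if (all(cz == 0)) NULL else function(rho, theta) {
    ph <- 0
    for (j in seq_along(cz)) {
      if (cz[j] != 0) ph <- ph + cz[j] * .zernike(j - 1, rho, theta)
    }
    2 * pi / lambda_um * ph
  }
  g <- .pupil_psf(phase_fun, wavelength_nm, pupil_mm, pixel_scale_arcmin,
                  side_px)
  .new_psf(g, pixel_scale_arcmin, wavelength_nm, pupil_mm)
}

#' Illustrative typical-aberration Zernike coefficients
#'
#' A plausible synthetic set of higher-order aberrations for a 3-mm pupil
#' (total higher-order RMS about 0.05 um), shipped so the natural-optics
#' observer can run out of the box.  These are illustrative values in the
#' range reported for normal adult eyes, not a reproduction of any published
#' population mean; supply your own coefficient vector for quantitative
#' work.
#'
#' @return List with `pupil_mm`, `wavelength_nm` and `osa_coeffs_microns`
#'   (OSA single-index order, j = 0 piston first).
#' @export
typical_aberrations <- function() {
  cz <- numeric(15)
  # j:      0..2 piston/tilt, 3 astig(-2), 4 defocus, 5 astig(2),
  #         6..9 trefoil/coma, 12 spherical
  cz[4]  <- 0.02   # oblique astigmatism
  cz[6]  <- 0.01   # vertical astigmatism
  cz[7]  <- 0.015  # oblique trefoil
  cz[8]  <- -0.02  # vertical coma
  cz[9]  <- 0.025  # horizontal coma
  cz[10] <- 0.01   # horizontal trefoil
  cz[13] <- 0.03   # primary spherical aberration
  list(pupil_mm = 3, wavelength_nm = 550, osa_coeffs_microns = cz)
}

#' Read a Zernike specification from JSON
#'
#' Expects `{pupil_mm, wavelength_nm, osa_coeffs_microns: [...]}`.
#'
#' @param path Path to a JSON file.
#' @return List in the format of [typical_aberrations()].
#' @export
read_zernike_json <- function(path) {
  z <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pupil_mm", "wavelength_nm", "osa_coeffs_microns")
  if (!all(need %in% names(z))) {
    stop("read_zernike_json(): missing fields: ",
         paste(setdiff(need, names(z)), collapse = ", "))
  }
  z
}

#' Blur a stimulus image with a PSF
#'
#' Linear 2-D convolution via zero-padded FFT, returning an image of the
#' input size.  Total flux is conserved because the PSF sums to one (edge
#' spill is retained by padding with the PSF half-width).
#'
#' @param image Numeric matrix (stimulus radiance map).
#' @param psf A `"psf"` object whose `pixel_scale_arcmin` matches
#'   `pixel_scale_arcmin`.
#' @param pixel_scale_arcmin Angular sampling of `image`.
#' @return Blurred matrix of the same size as `image`.
#' @export
apply_optics <- function(image, psf, pixel_scale_arcmin) {
  stopifnot(is.matrix(image), inherits(psf, "psf"))
  if (abs(psf$pixel_scale_arcmin - pixel_scale_arcmin) >
        1e-9 * pixel_scale_arcmin) {
    stop("apply_optics(): image and PSF pixel scales differ; resample the ",
         "PSF to the image scale first")
  }
  k <- psf$grid
  nr <- nrow(image) + nrow(k) - 1
  nc <- ncol(image) + ncol(k) - 1
  # pad to the full linear-convolution size
  pi_ <- matrix(0, nr, nc); pi_[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  pk <- matrix(0, nr, nc); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  conv <- Re(stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE)) /
    (nr * nc)
  # 'same' crop centred on the kernel centre
  r0 <- (nrow(k) - 1) / 2
  c0 <- (ncol(k) - 1) / 2
  conv[r0 + seq_len(nrow(image)), c0 + seq_len(ncol(image))]
}

#' Radial profile of a PSF
#'
#' Azimuthal average onto fine radial bins; used for width and first-zero
#' measurements.
#'
#' @param psf A `"psf"` object.
#' @param n_bins Number of radial bins.
#' @return Data frame with `radius_arcmin` and `intensity`.
#' @export
psf_radial_profile <- function(psf, n_bins = 200) {
  n <- nrow(psf$grid)
  ix <- (seq_len(n) - (n + 1) / 2) * psf$pixel_scale_arcmin
  r <- sqrt(outer(ix^2, ix^2, `+`))
  br <- seq(0, max(r), length.out = n_bins + 1)
  bin <- findInterval(r, br, rightmost.closed = TRUE)
  prof <- as.numeric(tapply(psf$grid, bin, mean))
  mid <- (br[-1] + br[-length(br)]) / 2
  data.frame(radius_arcmin = mid[seq_along(prof)], intensity = prof)
}
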