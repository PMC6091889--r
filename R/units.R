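# Angular and radiometric conversions shared by every analysis stage.
# All angles are carried in arcmin internally; degrees appear only at I/O
# boundaries (mosaic fields of view, pixel scales supplied in deg).

#' Convert a pixel extent to arcmin
#'
#' The raster scale of the stimulus display is expressed in pixels per degree
#' (415 px/deg for the system emulated here), so `n_px` pixels subtend
#' `n_px / px_per_deg * 60` arcmin.
#'
#' @param n_px Extent in pixels (>= 1).
#' @param px_per_deg Pixels per degree of visual angle (default 415).
#' @return Extent in arcmin.
#' @seealso [arcmin_to_pixels()]
#' @export
#' @examples
#' pixels_to_arcmin(3)   # smallest stimulus, 0.43 arcmin
#' pixels_to_arcmin(64)  # largest stimulus, 9.25 arcmin
pixels_to_arcmin <- function(n_px, px_per_deg = 415) {
  stopifnot(is.numeric(n_px), is.numeric(px_per_deg))
  if (any(n_px < 1) || any(px_per_deg <= 0)) {
    stop("pixels_to_arcmin(): n_px must be >= 1 and px_per_deg > 0")
  }
  n_px / px_per_deg * 60
}

#' Convert an arcmin extent to pixels
#'
#' Exact inverse of [pixels_to_arcmin()].
#'
#' @param arcmin Extent in arcmin (> 0).
#' @param px_per_deg Pixels per degree of visual angle (default 415).
#' @return Extent in (possibly fractional) pixels.
#' @export
arcmin_to_pixels <- function(arcmin, px_per_deg = 415) {
  stopifnot(is.numeric(arcmin), is.numeric(px_per_deg))
  if (any(arcmin <= 0) || any(px_per_deg <= 0)) {
    stop("arcmin_to_pixels(): arguments must be positive")
  }
  arcmin / 60 * px_per_deg
}

#' Area of a circular stimulus
#'
#' @param diameter_arcmin Disk diameter in arcmin (> 0).
#' @return Area in arcmin^2 (`pi * d^2 / 4`).
#' @export
disk_area <- function(diameter_arcmin) {
  if (any(!is.finite(diameter_arcmin)) || any(diameter_arcmin <= 0)) {
    stop("disk_area(): diameter must be positive and finite")
  }
  pi * diameter_arcmin^2 / 4
}

#' Diameter of a disk with a given area
#'
#' Inverse of [disk_area()]; used to express a summation area as an
#' equivalent circular diameter.
#'
#' @param area_arcmin2 Area in arcmin^2 (> 0).
#' @return Diameter in arcmin (`2 * sqrt(area / pi)`).
#' @export
disk_diameter <- function(area_arcmin2) {
  if (any(!is.finite(area_arcmin2)) || any(area_arcmin2 <= 0)) {
    stop("disk_diameter(): area must be positive and finite")
  }
  2 * sqrt(area_arcmin2 / pi)
}

#' Threshold energy of a detected stimulus
#'
#' Threshold energy is the product of threshold luminance (cd/m^2), stimulus
#' area (arcmin^2) and stimulus duration (s).  Summation curves plot its
#' decimal logarithm against log stimulus area.
#'
#' @param luminance_cd_m2 Threshold luminance in cd/m^2.
#' @param area_arcmin2 Stimulus area in arcmin^2.
#' @param duration_s Stimulus duration in seconds.
#' @return Object of class `"threshold_energy"`: list with `value`
#'   (cd/m^2 * arcmin^2 * s) and `log10_value`.
#' @export
threshold_energy <- function(luminance_cd_m2, area_arcmin2, duration_s) {
  vals <- c(luminance_cd_m2, area_arcmin2, duration_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("threshold_energy(): all factors must be positive and finite")
  }
  value <- luminance_cd_m2 * area_arcmin2 * duration_s
  structure(list(value = value, log10_value = log10(value)),
            class = "threshold_energy")
}

#' Geometry of a Gaussian pooling kernel
#'
#' The pooling kernel is parameterized by its Gaussian standard deviation
#' `sigma`.  Its nominal radius is taken as `2 * sigma`, so the kernel area is
#' `pi * (2 sigma)^2`; the full width at half maximum is
#' `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param sigma_arcmin Gaussian standard deviation in arcmin (> 0).
#' @return Object of class `"kernel_geometry"`: list with `sigma_arcmin`,
#'   `fwhm_arcmin`, `radius_arcmin` and `area_arcmin2`.
#' @export
#' @examples
#' kernel_geometry(1.6)$fwhm_arcmin  # 3.77 arcmin
kernel_geometry <- function(sigma_arcmin) {
  if (!is.finite(sigma_arcmin) || sigma_arcmin <= 0) {
    stop("kernel_geometry(): sigma must be positive and finite")
  }
  radius <- 2 * sigma_arcmin
  structure(list(
    sigma_arcmin  = sigma_arcmin,
    fwhm_arcmin   = 2 * sqrt(2 * log(2)) * sigma_arcmin,
    radius_arcmin = radius,
    area_arcmin2  = pi * radius^2
  ), class = "kernel_geometry")
}

#' Specification of a circular increment stimulus
#'
#' @param diameter_px Stimulus diameter in display pixels.
#' @param pixels_per_degree Raster scale (default 415 px/deg).
#' @param wavelength_nm Stimulus wavelength (default 550 nm).
#' @param duration_s Stimulus duration (default 0.125 s: three frames at
#'   16 Hz).
#' @param luminance_cd_m2 Optional stimulus luminance at full intensity.
#' @return Object of class `"stimulus_spec"` with derived `diameter_arcmin`
#'   and `area_arcmin2` fields.
#' @export
stimulus_spec <- function(diameter_px, pixels_per_degree = 415,
                          wavelength_nm = 550, duration_s = 0.125,
                          luminance_cd_m2 = NA_real_) {
  d_arcmin <- pixels_to_arcmin(diameter_px, pixels_per_degree)
  structure(list(
    diameter_px       = diameter_px,
    pixels_per_degree = pixels_per_degree,
    diameter_arcmin   = d_arcmin,
    area_arcmin2      = disk_area(d_arcmin),
    wavelength_nm     = wavelength_nm,
    duration_s        = duration_s,
    luminance_cd_m2   = luminance_cd_m2
  ), class = "stimulus_spec")
}

#' Default stimulus diameters
#'
#' The ten psychophysical stimulus diameters (3 to 64 display pixels at
#' 415 px/deg) and, optionally, the four additional diameters inserted near
#' the expected summation break when simulating the computational observer.
#'
#' @param extended If `TRUE`, return the 14-value model grid; otherwise the
#'   10 psychophysical diameters.
#' @return Numeric vector of diameters in arcmin.
#' @export
default_stimulus_diameters <- function(extended = FALSE) {
  base_px <- c(3, 4, 6, 8, 12, 16, 24, 32, 48, 64)
  d <- pixels_to_arcmin(base_px)
  if (extended) sort(c(d, c(1.35, 2.00, 2.70, 3.10))) else d
}
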