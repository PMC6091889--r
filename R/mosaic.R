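# Hexagonal cone mosaic generation and Poisson isomerization responses.
#
# Radiometric chain per cone and 5-ms time bin:
#   mean isomerizations = photon rate (photons/um^2/s) at the cone position
#     x aperture collecting area (circular 3-um top hat)
#     x (1 - 10^-OD)            photopigment axial optical density, 0.5
#     x class sensitivity at the stimulus wavelength (pigment template)
#     x quantal efficiency      0.67
#     x bin duration            0.005 s
# A constant background pedestal (mean isomerizations per bin, config
# scalar) is added to every bin; the stimulus contributes only in on-bins.

#' Spectral sensitivity of a cone class
#'
#' Analytic A1 visual-pigment absorbance template (Govardovskii et al. 2000
#' alpha-band form) with peak wavelengths 559 nm (L), 530 nm (M) and 421 nm
#' (S), normalized to 1 at peak.  For the narrowband 550-nm stimulus
#' modeled here only the value at 550 nm matters, so the template replaces
#' full tabulated fundamentals; pre-receptoral filtering is not included.
#'
#' @param class Character vector of cone classes (`"L"`, `"M"`, `"S"`).
#' @param wavelength_nm Wavelength in nm.
#' @return Relative sensitivity in `[0, 1]`.
#' @export
cone_sensitivity <- function(class, wavelength_nm = 550) {
  peaks <- c(L = 559, M = 530, S = 421)
  lm <- peaks[toupper(class)]
  if (any(is.na(lm))) stop("cone_sensitivity(): unknown cone class")
  x <- lm / wavelength_nm
  a <- 0.8795 + 0.0459 * exp(-(lm - 300)^2 / 11940)
  b <- 0.922; cc <- 1.104
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  unname(1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D))
}

#' Build a hexagonally packed cone mosaic
#'
#' Generates a hexagonal lattice with spacing set by the requested areal
#' density (`spacing = sqrt(2 / (sqrt(3) * density))`), clipped to a square
#' field of view, with optional positional jitter.
#'
#' @param fov_deg Side of the square field of view in degrees (default
#'   0.26).
#' @param density_cones_per_mm2 Cone density (default 104000).
#' @param mm_per_deg Retinal magnification (default 0.30 mm/deg).
#' @param jitter Positional jitter as a fraction of the lattice spacing
#'   (default 0).
#' @param seed Optional seed (used only when `jitter > 0`).
#' @return Object of class `"cone_mosaic"`: list with `x_deg`, `y_deg`
#'   (positions relative to mosaic center), `classes` (unassigned until
#'   [assign_cone_classes()]), `density_cones_per_mm2`, `aperture_um`,
#'   `integration_time_s`, `mm_per_deg`, `n_cones`, `central_cone` (index
#'   of the cone nearest the origin).
#' @export
build_hex_mosaic <- function(fov_deg = 0.26, density_cones_per_mm2 = 104000,
                             mm_per_deg = 0.30, jitter = 0, seed = NULL) {
  stopifnot(fov_deg > 0, density_cones_per_mm2 > 0, mm_per_deg > 0,
            jitter >= 0)
  spacing_mm <- sqrt(2 / (sqrt(3) * density_cones_per_mm2))
  spacing_deg <- spacing_mm / mm_per_deg
  half <- fov_deg / 2
  row_h <- spacing_deg * sqrt(3) / 2
  n_rows <- floor(half / row_h)
  rows <- seq(-n_rows, n_rows) * row_h
  xs <- ys <- numeric(0)
  n_cols <- ceiling(half / spacing_deg) + 1
  for (k in seq_along(rows)) {
    offset <- if ((k - n_rows - 1) %% 2 == 0) 0 else spacing_deg / 2
    cx <- seq(-n_cols, n_cols) * spacing_deg + offset
    cx <- cx[abs(cx) <= half]
    xs <- c(xs, cx)
    ys <- c(ys, rep(rows[k], length(cx)))
  }
  keep <- abs(xs) <= half & abs(ys) <= half
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 7) {
    stop("build_hex_mosaic(): field of view / density give fewer than 7 ",
         "cones")
  }
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    xs <- xs + stats::rnorm(length(xs), 0, jitter * spacing_deg)
    ys <- ys + stats::rnorm(length(ys), 0, jitter * spacing_deg)
  }
  central <- which.min(xs^2 + ys^2)
  structure(list(
    x_deg = xs, y_deg = ys, classes = rep(NA_character_, length(xs)),
    density_cones_per_mm2 = density_cones_per_mm2,
    aperture_um = 3, integration_time_s = 0.005,
    mm_per_deg = mm_per_deg, fov_deg = fov_deg,
    spacing_deg = spacing_deg, n_cones = length(xs),
    central_cone = central
  ), class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("Hexagonal cone mosaic: %d cones over %.3g x %.3g deg\n",
              x$n_cones, x$fov_deg, x$fov_deg))
  cat(sprintf("  density %.5g cones/mm^2, spacing %.4g deg, aperture %g um\n",
              x$density_cones_per_mm2, x$spacing_deg, x$aperture_um))
  if (!all(is.na(x$classes))) {
    cat("  classes:", paste(names(table(x$classes)),
                            table(x$classes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign L/M/S classes to mosaic cones
#'
#' Classes are drawn independently per cone with the stated probabilities.
#'
#' @param mosaic A `"cone_mosaic"`.
#' @param ratio Named or ordered numeric vector of L, M, S probabilities
#'   summing to 1 (default `c(0.67, 0.33, 0)`).
#' @param seed Optional seed.
#' @return The mosaic with its `classes` field filled in.
#' @export
assign_cone_classes <- function(mosaic, ratio = c(L = 0.67, M = 0.33, S = 0),
                                seed = NULL) {
  stopifnot(inherits(mosaic, "cone_mosaic"), length(ratio) == 3)
  if (any(ratio < 0)) stop("assign_cone_classes(): negative ratio")
  if (abs(sum(ratio) - 1) > 1e-6) {
    stop("assign_cone_classes(): ratio must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  mosaic$classes <- sample(c("L", "M", "S"), mosaic$n_cones,
                           replace = TRUE, prob = ratio)
  mosaic
}

#' Mean isomerizations per cone and time bin
#'
#' The retinal photon-rate image is first integrated over the circular cone
#' aperture (convolution with a 3-um top hat whose integral is the aperture
#' collecting area, so sub-aperture structure is physically summed rather
#' than point-sampled), sampled at each cone position by bilinear
#' interpolation, and passed through the radiometric chain described above.
#' The returned matrix has one row per cone and one column per 5-ms bin;
#' the background pedestal contributes to every bin and the stimulus only
#' to the on-bins.
#'
#' @param retinal_image Matrix of stimulus photon rates
#'   (photons/um^2/s) at the retina, already blurred by the optics.
#' @param pixel_scale_arcmin Angular sampling of `retinal_image`; the image
#'   center is aligned with the mosaic center.
#' @param mosaic A `"cone_mosaic"` with classes assigned.
#' @param n_bins Number of 5-ms bins in the epoch (default 31: 155 ms).
#' @param on_bins Indices of bins during which the stimulus is on (default
#'   `6:25`, a centered 100-ms window).
#' @param qe Isomerization quantal efficiency (default 0.67).
#' @param od Photopigment optical density (default 0.5).
#' @param background_mean_per_bin Pedestal mean isomerizations per bin
#'   added to every cone and bin (default 10, a photopic resting level).
#' @param wavelength_nm Stimulus wavelength for the class sensitivity.
#' @return `n_cones x n_bins` matrix of mean isomerization counts.
#' @export
mean_isomerizations <- function(retinal_image, pixel_scale_arcmin, mosaic,
                                n_bins = 31, on_bins = 6:25, qe = 0.67,
                                od = 0.5, background_mean_per_bin = 10,
                                wavelength_nm = 550) {
  stopifnot(inherits(mosaic, "cone_mosaic"), is.matrix(retinal_image))
  if (any(is.na(mosaic$classes))) {
    stop("mean_isomerizations(): assign cone classes first")
  }
  if (max(on_bins) > n_bins) {
    stop("mean_isomerizations(): stimulus window exceeds the epoch")
  }
  # integrate over the cone aperture: convolve with a top hat whose
  # integral equals the aperture area in um^2, so the sampled value is the
  # collected photon rate (photons/s)
  um_per_px <- pixel_scale_arcmin / 60 * mosaic$mm_per_deg * 1000
  ap_radius_px <- (mosaic$aperture_um / 2) / um_per_px
  collected <- .aperture_integrate(retinal_image, ap_radius_px) *
    um_per_px^2
  # cone positions in image pixel coordinates (image center = mosaic center)
  nr <- nrow(retinal_image); nc <- ncol(retinal_image)
  x_px <- mosaic$x_deg * 60 / pixel_scale_arcmin + (nc + 1) / 2
  y_px <- mosaic$y_deg * 60 / pixel_scale_arcmin + (nr + 1) / 2
  if (any(x_px < 1 | x_px > nc | y_px < 1 | y_px > nr)) {
    stop("mean_isomerizations(): cone outside the image footprint")
  }
  x0 <- pmin(floor(x_px), nc - 1); y0 <- pmin(floor(y_px), nr - 1)
  fx <- x_px - x0; fy <- y_px - y0
  rate <- collected[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    collected[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    collected[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    collected[cbind(y0 + 1, x0 + 1)] * fx * fy
  sens <- cone_sensitivity(mosaic$classes, wavelength_nm)
  stim_mean <- rate * (1 - 10^(-od)) * sens * qe *
    mosaic$integration_time_s
  means <- matrix(background_mean_per_bin, mosaic$n_cones, n_bins)
  means[, on_bins] <- means[, on_bins] + stim_mean
  means
}

# Convolve an image with an anti-aliased circular top hat of the given
# pixel radius (unit height), via zero-padded FFT ('same' output).  The
# kernel sum approximates the disk area in pixel^2.
.aperture_integrate <- function(img, radius_px) {
  side <- 2 * ceiling(radius_px + 1) + 1
  ix <- seq_len(side) - (side + 1) / 2
  k <- pmin(pmax(radius_px - sqrt(outer(ix^2, ix^2, `+`)) + 0.5, 0), 1)
  nr <- nrow(img) + side - 1
  nc <- ncol(img) + side - 1
  pi_ <- matrix(0, nr, nc); pi_[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  pk <- matrix(0, nr, nc); pk[seq_len(side), seq_len(side)] <- k
  conv <- Re(stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE)) /
    (nr * nc)
  off <- (side - 1) / 2
  conv[off + seq_len(nrow(img)), off + seq_len(ncol(img))]
}

#' Draw Poisson response instances
#'
#' Independent Poisson draws per cone, bin and instance.
#'
#' @param means `n_cones x n_bins` matrix of mean counts.
#' @param n_instances Number of instances (default 2000).
#' @param seed Optional seed.
#' @return Object of class `"response_instances"`: list with `counts`
#'   (`n_instances x (n_cones * n_bins)` integer matrix; bin index varies
#'   fastest within a cone), `n_cones`, `n_bins`, `n_instances`.
#' @export
draw_response_instances <- function(means, n_instances = 2000, seed = NULL) {
  stopifnot(is.matrix(means))
  if (any(means < 0)) stop("draw_response_instances(): negative mean")
  if (!is.null(seed)) set.seed(seed)
  n_cell <- length(means)
  # rows: instances; columns: flattened cone x bin means
  flat <- as.numeric(t(means))   # bin fastest within cone
  counts <- matrix(stats::rpois(n_instances * n_cell, rep(flat, each = n_instances)),
                   nrow = n_instances, ncol = n_cell)
  structure(list(counts = counts, n_cones = nrow(means),
                 n_bins = ncol(means), n_instances = n_instances),
            class = "response_instances")
}
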