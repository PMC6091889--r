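# Delivery-location filtering, intratrial stimulus-travel statistics, and
# subpixel DFT-based image registration for transverse chromatic
# aberration.
#
# Coordinate convention for delivery traces: arcmin relative to the raster
# center, +x right, +y down (image convention).

#' Filter delivery traces by the inclusion window
#'
#' A square window of the given side length is centered on the median of
#' all delivery positions (both axes, all frames); a trace is retained only
#' if all three of its frames fall inside the closed window (half-window
#' boundary points are included).
#'
#' @param traces Data frame with columns `fx1, fy1, fx2, fy2, fx3, fy3`
#'   (arcmin) and optionally `trial_id`.
#' @param window_arcmin Window side length (default 4.75 arcmin).
#' @return The subset of `traces` passing the criterion, with an attribute
#'   `window_center` (the median delivery location).
#' @export
filter_valid_deliveries <- function(traces, window_arcmin = 4.75) {
  cols <- c("fx1", "fy1", "fx2", "fy2", "fx3", "fy3")
  stopifnot(is.data.frame(traces), all(cols %in% names(traces)))
  if (nrow(traces) == 0) stop("filter_valid_deliveries(): empty input")
  xs <- unlist(traces[c("fx1", "fx2", "fx3")], use.names = FALSE)
  ys <- unlist(traces[c("fy1", "fy2", "fy3")], use.names = FALSE)
  cx <- stats::median(xs); cy <- stats::median(ys)
  h <- window_arcmin / 2
  ok <- rep(TRUE, nrow(traces))
  for (i in 1:3) {
    ok <- ok &
      abs(traces[[paste0("fx", i)]] - cx) <= h &
      abs(traces[[paste0("fy", i)]] - cy) <= h
  }
  out <- traces[ok, , drop = FALSE]
  attr(out, "window_center") <- c(x = cx, y = cy)
  out
}

#' Total intratrial stimulus travel
#'
#' Sum of the lengths of the vectors connecting the first and second and
#' the second and third delivery locations.
#'
#' @param trace A 3 x 2 matrix of frame positions (arcmin), or a one-row
#'   data frame with `fx1 ... fy3` columns.
#' @return Travel in arcmin.
#' @export
intratrial_travel <- function(trace) {
  if (is.data.frame(trace)) {
    stopifnot(nrow(trace) == 1)
    trace <- matrix(c(trace$fx1, trace$fy1, trace$fx2, trace$fy2,
                      trace$fx3, trace$fy3), 3, 2, byrow = TRUE)
  }
  if (!is.matrix(trace) || !all(dim(trace) == c(3, 2))) {
    stop("intratrial_travel(): trace must contain exactly 3 (x, y) ",
         "positions")
  }
  d <- diff(trace)
  sum(sqrt(rowSums(d^2)))
}

#' Travel for every trace in a table
#'
#' @param traces Data frame with `fx1 ... fy3` columns.
#' @return Numeric vector of per-trial travel (arcmin).
#' @export
intratrial_travel_all <- function(traces) {
  sqrt((traces$fx2 - traces$fx1)^2 + (traces$fy2 - traces$fy1)^2) +
    sqrt((traces$fx3 - traces$fx2)^2 + (traces$fy3 - traces$fy2)^2)
}

#' Scalar dispersion of delivery locations
#'
#' The standard deviation of a 2-D point cloud is scalarized as the mean of
#' the per-axis standard deviations; both per-axis values are returned as
#' an attribute.
#'
#' @param positions n x 2 matrix (or data frame) of (x, y) positions.
#' @return Scalar dispersion in arcmin with attribute `per_axis`.
#' @export
delivery_dispersion <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) {
    stop("delivery_dispersion(): need at least 2 positions")
  }
  sds <- apply(positions, 2, stats::sd)
  structure(mean(sds), per_axis = c(x = sds[[1]], y = sds[[2]]))
}

# Upsampled cross-correlation in a small neighbourhood of an initial shift,
# evaluated by matrix-multiply DFTs (no large zero-padded transform).
.dft_ups <- function(cross_f, nr, nc, ups, row0, col0, nhood) {
  n_out <- ceiling(nhood * ups)
  fr <- .fft_freqs(nr)
  fc <- .fft_freqs(nc)
  rows <- row0 + (seq_len(n_out) - 1 - floor(n_out / 2)) / ups
  cols <- col0 + (seq_len(n_out) - 1 - floor(n_out / 2)) / ups
  kr <- exp(2i * pi / nr * outer(rows, fr))   # n_out x nr
  kc <- exp(2i * pi / nc * outer(fc, cols))   # nc x n_out
  cc <- Re(kr %*% cross_f %*% kc)
  peak <- which.max(cc)
  pr <- (peak - 1) %% n_out + 1
  pc <- (peak - 1) %/% n_out + 1
  c(row = rows[pr], col = cols[pc], val = cc[pr, pc])
}

.fft_freqs <- function(n) {
  f <- seq_len(n) - 1
  f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
  f
}

#' Register an image pair by DFT cross-correlation
#'
#' Finds the translation of `imageB` relative to `imageA` from the peak of
#' their cross-correlation, computed in the Fourier domain, then refines it
#' to subpixel precision with a matrix-multiply upsampled DFT around the
#' integer peak.  Images are windowed (Hann) before transforming to
#' suppress wrap-around artifacts; set `window = FALSE` for periodic
#' inputs.
#'
#' @param imageA,imageB Equal-size numeric matrices.
#' @param upsample Subpixel upsampling factor (default 20, i.e. 1/20 px).
#' @param window Apply a Hann window before the FFT (default `TRUE`).
#' @return Object of class `"registration_offset"`: list with `dx_px`,
#'   `dy_px` (columnwise/rowwise shift of B relative to A) and `peak_corr`
#'   (normalized correlation coefficient at the recovered shift).
#' @export
register_pair_dft <- function(imageA, imageB, upsample = 20,
                              window = TRUE) {
  stopifnot(is.matrix(imageA), is.matrix(imageB),
            all(dim(imageA) == dim(imageB)))
  if (stats::sd(imageA) < 1e-12 || stats::sd(imageB) < 1e-12) {
    stop("register_pair_dft(): flat image; registration is degenerate")
  }
  nr <- nrow(imageA); nc <- ncol(imageA)
  a <- imageA - mean(imageA)
  b <- imageB - mean(imageB)
  if (window) {
    hr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
    hc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
    w <- outer(hr, hc)
    a <- a * w; b <- b * w
  }
  fa <- stats::fft(a); fb <- stats::fft(b)
  cross_f <- Conj(fa) * fb
  cc <- Re(stats::fft(cross_f, inverse = TRUE))
  peak <- which.max(cc)
  pr <- (peak - 1) %% nr
  pc <- (peak - 1) %/% nr
  if (pr > nr / 2) pr <- pr - nr          # wrap to signed shifts
  if (pc > nc / 2) pc <- pc - nc
  if (upsample > 1) {
    ref <- .dft_ups(cross_f, nr, nc, upsample, pr, pc, nhood = 3)
    pr <- ref["row"]; pc <- ref["col"]
  }
  # normalized correlation at the recovered (rounded) shift
  peak_corr <- .shifted_correlation(imageA, imageB, round(pr), round(pc))
  structure(list(dy_px = unname(pr), dx_px = unname(pc),
                 peak_corr = peak_corr),
            class = "registration_offset")
}

# Pearson correlation between A and B circularly shifted back by the
# integer offset (r rows, c cols).
.shifted_correlation <- function(A, B, r, c) {
  nr <- nrow(A); nc <- ncol(A)
  ri <- ((seq_len(nr) - 1 + r) %% nr) + 1
  ci <- ((seq_len(nc) - 1 + c) %% nc) + 1
  stats::cor(as.numeric(A), as.numeric(B[ri, ci]))
}

#' Transverse chromatic aberration from per-frame offsets
#'
#' The TCA of a session video is the componentwise median of its per-frame
#' registration offsets; the overall TCA is the mean of the pre- and
#' post-session values.
#'
#' @param pre_session,post_session Data frames (or lists of
#'   `"registration_offset"`) with `dx_px` and `dy_px` per frame; pass the
#'   same object twice if only one session was measured.
#' @return Named vector `c(dx, dy)` in pixels.
#' @export
tca_from_offsets <- function(pre_session, post_session = pre_session) {
  med <- function(s) {
    if (is.data.frame(s)) {
      if (nrow(s) == 0) stop("tca_from_offsets(): empty session")
      c(stats::median(s$dx_px), stats::median(s$dy_px))
    } else {
      if (length(s) == 0) stop("tca_from_offsets(): empty session")
      dx <- vapply(s, `[[`, numeric(1), "dx_px")
      dy <- vapply(s, `[[`, numeric(1), "dy_px")
      c(stats::median(dx), stats::median(dy))
    }
  }
  pre <- med(pre_session); post <- med(post_session)
  c(dx = (pre[1] + post[1]) / 2, dy = (pre[2] + post[2]) / 2)
}
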