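# Threshold-energy-versus-area curves and Ricco's-area estimation.
#
# Ricco's area is the breakpoint of a two-segment regression of log10
# threshold energy on log10 stimulus area: the first segment is flat
# (complete summation, slope fixed at zero), the second has free slope, and
# the segments are constrained to meet at the breakpoint.

#' Construct a summation curve from per-size thresholds
#'
#' Threshold intensities (in normalized `[0, 1]` units) are converted to
#' luminance with the supplied calibration, multiplied by stimulus area and
#' duration to obtain threshold energy, and returned on log-log axes sorted
#' by area.
#'
#' @param thresholds Data frame with columns `diameter_arcmin` and
#'   `threshold_intensity` (one row per stimulus size); an optional
#'   `size_id` column is carried through.
#' @param calibration List with `max_luminance_cd_m2` (luminance at
#'   intensity 1; intensity maps linearly to luminance) and `duration_s`.
#' @param condition Optional condition label.
#' @return Object of class `"summation_curve"`: data frame with columns
#'   `log10_area`, `log10_energy` (and `diameter_arcmin`), plus attributes
#'   `condition` and `calibration`.
#' @export
build_summation_curve <- function(thresholds, calibration,
                                  condition = "unlabeled") {
  stopifnot(is.data.frame(thresholds),
            all(c("diameter_arcmin", "threshold_intensity") %in%
                  names(thresholds)))
  if (is.null(calibration$max_luminance_cd_m2) ||
      is.null(calibration$duration_s)) {
    stop("build_summation_curve(): calibration must supply ",
         "max_luminance_cd_m2 and duration_s")
  }
  th <- thresholds[order(thresholds$diameter_arcmin), , drop = FALSE]
  if (any(duplicated(th$diameter_arcmin))) {
    stop("build_summation_curve(): one threshold per stimulus size required")
  }
  area <- disk_area(th$diameter_arcmin)
  lum <- th$threshold_intensity * calibration$max_luminance_cd_m2
  energy <- vapply(seq_along(area), function(i) {
    threshold_energy(lum[i], area[i], calibration$duration_s)$value
  }, numeric(1))
  out <- data.frame(log10_area = log10(area), log10_energy = log10(energy),
                    diameter_arcmin = th$diameter_arcmin)
  if (!is.null(th$size_id)) out$size_id <- th$size_id
  structure(out, class = c("summation_curve", "data.frame"),
            condition = condition, calibration = calibration)
}

#' Bare summation curve from precomputed log-log points
#'
#' @param log10_area,log10_energy Numeric vectors (areas strictly
#'   increasing).
#' @param condition Optional label.
#' @return A `"summation_curve"` object.
#' @export
summation_curve <- function(log10_area, log10_energy,
                            condition = "unlabeled") {
  stopifnot(length(log10_area) == length(log10_energy))
  if (is.unsorted(log10_area, strictly = TRUE)) {
    stop("summation_curve(): areas must be strictly increasing")
  }
  structure(data.frame(log10_area = log10_area,
                       log10_energy = log10_energy),
            class = c("summation_curve", "data.frame"),
            condition = condition)
}

# Conditional least squares at a fixed breakpoint b:
# y_i = L                      for x_i <= b
# y_i = L + s * (x_i - b)      for x_i >  b
# Linear in (L, s); closed form via the normal equations.
.two_seg_rss <- function(b, x, y) {
  h <- pmax(x - b, 0)
  n <- length(x)
  sh <- sum(h); shh <- sum(h * h)
  sy <- sum(y); shy <- sum(h * y)
  det <- n * shh - sh * sh
  if (det < 1e-12) {                     # no points beyond b: flat line only
    L <- sy / n
    return(c(rss = sum((y - L)^2), L = L, s = 0))
  }
  L <- (shh * sy - sh * shy) / det
  s <- (n * shy - sh * sy) / det
  r <- y - L - s * h
  c(rss = sum(r * r), L = L, s = s)
}

#' Fit a two-segment summation regression
#'
#' Least squares over the flat level, breakpoint and second-segment slope,
#' with the first-segment slope fixed at zero and continuity at the
#' breakpoint.  The breakpoint is located by a dense grid search over the
#' observed log-area range (closed-form conditional least squares at each
#' candidate) followed by local refinement with `optimize()`, so the global
#' optimum is found reproducibly.
#'
#' @param curve A `"summation_curve"` (or data frame with `log10_area` and
#'   `log10_energy`), with at least 4 points.
#' @param n_grid Number of breakpoint candidates (default 1000).
#' @return Object of class `"two_segment_fit"`: list with `flat_level`,
#'   `breakpoint_log_area`, `second_slope`, `ricco_area_arcmin2`,
#'   `ricco_diameter_arcmin`, `rss`, and `boundary` (`TRUE` when the best
#'   breakpoint sits at the edge of the search range, flagging the absence
#'   of an interior summation knee).
#' @export
fit_two_segment <- function(curve, n_grid = 1000) {
  x <- curve$log10_area
  y <- curve$log10_energy
  stopifnot(length(x) >= 4, !is.unsorted(x))
  lo <- min(x); hi <- max(x)
  bs <- seq(lo, hi, length.out = n_grid)
  # vectorized conditional LS over all breakpoint candidates
  H <- outer(bs, x, function(b, xx) pmax(xx - b, 0))   # n_grid x n
  n <- length(x)
  sh <- rowSums(H); shh <- rowSums(H * H)
  sy <- sum(y); syy <- sum(y * y); shy <- as.numeric(H %*% y)
  det <- n * shh - sh * sh
  flat_only <- det < 1e-12
  det[flat_only] <- 1
  L <- (shh * sy - sh * shy) / det
  s <- (n * shy - sh * sy) / det
  L[flat_only] <- sy / n
  s[flat_only] <- 0
  rss <- syy - 2 * L * sy - 2 * s * shy + L^2 * n + 2 * L * s * sh +
    s^2 * shh
  i <- which.min(rss)
  # refine within the neighbouring grid cells
  lo_i <- bs[max(i - 1, 1)]
  hi_i <- bs[min(i + 1, n_grid)]
  ref <- stats::optimize(function(b) .two_seg_rss(b, x, y)[1],
                         interval = c(lo_i, hi_i), tol = 1e-9)
  b <- if (ref$objective < rss[i] - 1e-12) ref$minimum else bs[i]
  sol <- .two_seg_rss(b, x, y)
  ricco_area <- 10^b
  # degenerate when the knee sits at the search edge or the broken stick
  # does not improve on a single flat line (no interior summation knee)
  rss_flat <- sum((y - mean(y))^2)
  at_edge <- (b - lo < 1e-6 * (hi - lo)) || (hi - b < 1e-6 * (hi - lo))
  structure(list(
    flat_level = unname(sol["L"]),
    breakpoint_log_area = b,
    second_slope = unname(sol["s"]),
    ricco_area_arcmin2 = ricco_area,
    ricco_diameter_arcmin = disk_diameter(ricco_area),
    rss = unname(sol["rss"]),
    boundary = at_edge || unname(sol["rss"]) >= rss_flat - 1e-10
  ), class = "two_segment_fit")
}

#' @export
print.two_segment_fit <- function(x, ...) {
  cat("Two-segment summation fit\n")
  cat(sprintf("  flat level: %.3f log10 energy\n", x$flat_level))
  cat(sprintf("  Ricco's area: %.3f arcmin^2 (diameter %.2f arcmin)\n",
              x$ricco_area_arcmin2, x$ricco_diameter_arcmin))
  cat(sprintf("  second-segment slope: %.3f   RSS: %.4g%s\n",
              x$second_slope, x$rss,
              if (x$boundary) "   [breakpoint at search boundary]" else ""))
  invisible(x)
}

#' Bootstrap the Ricco's-area estimate
#'
#' Trials are resampled with replacement within each stimulus size
#' (stratified bootstrap), psychometric functions refitted (warm-started at
#' the point-estimate parameters), the summation curve rebuilt and the
#' two-segment regression refitted.  Replicates whose psychometric refit is
#' degenerate (e.g. an all-yes resample) are recorded as missing.
#'
#' @param trials Data frame of trials with columns `diameter_arcmin`,
#'   `intensity`, `response` (and optionally `valid`, which filters rows).
#' @param calibration As in [build_summation_curve()].
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @param statistic Which fitted quantity to collect: `"ricco_area"`
#'   (default), `"ricco_diameter"`, `"second_slope"` or `"flat_level"`.
#' @param log10_intensity Passed to [fit_yes_no_psychometric()]
#'   (default `TRUE`: thresholds vary over two decades across sizes).
#' @return Object of class `"bootstrap_interval"`: list with `n_reps`,
#'   `samples` (length `n_reps`, `NA` for failed replicates), `lo_p5`,
#'   `hi_p95`, `point` (the full-data estimate) and `n_failed`.
#' @export
bootstrap_ricco <- function(trials, calibration, n_reps = 500, seed = NULL,
                            statistic = c("ricco_area", "ricco_diameter",
                                          "second_slope", "flat_level"),
                            log10_intensity = TRUE) {
  statistic <- match.arg(statistic)
  if (!is.null(trials$valid)) trials <- trials[as.logical(trials$valid), ]
  stopifnot(nrow(trials) > 0,
            all(c("diameter_arcmin", "intensity", "response") %in%
                  names(trials)))
  if (!is.null(seed)) set.seed(seed)
  sizes <- sort(unique(trials$diameter_arcmin))
  groups <- lapply(sizes, function(d) {
    g <- trials[trials$diameter_arcmin == d, c("intensity", "response")]
    if (nrow(g) == 0) stop("bootstrap_ricco(): empty size group")
    g
  })

  # point estimate (also provides warm starts for the replicates)
  point_fits <- lapply(groups, function(g) {
    fit_yes_no_psychometric(g$intensity, g$response,
                            log10_intensity = log10_intensity)
  })
  warm <- lapply(point_fits, function(f) c(f$alpha, f$beta))
  make_fit <- function(fits) {
    th <- data.frame(
      diameter_arcmin = sizes,
      threshold_intensity = vapply(fits, `[[`, numeric(1), "threshold_78"))
    fit_two_segment(build_summation_curve(th, calibration))
  }
  pick <- function(fit) switch(statistic,
    ricco_area = fit$ricco_area_arcmin2,
    ricco_diameter = fit$ricco_diameter_arcmin,
    second_slope = fit$second_slope,
    flat_level = fit$flat_level)
  point_fit <- make_fit(point_fits)

  samples <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    rep_fits <- vector("list", length(groups))
    ok <- TRUE
    for (j in seq_along(groups)) {
      g <- groups[[j]]
      idx <- sample.int(nrow(g), nrow(g), replace = TRUE)
      f <- tryCatch(
        fit_yes_no_psychometric(g$intensity[idx], g$response[idx],
                                log10_intensity = log10_intensity,
                                start = warm[[j]]),
        error = function(e) NULL)
      if (is.null(f) || !is.finite(f$threshold_78) ||
            f$threshold_78 <= 0) { ok <- FALSE; break }
      rep_fits[[j]] <- f
    }
    if (ok) {
      samples[r] <- tryCatch(pick(make_fit(rep_fits)),
                             error = function(e) NA_real_)
    }
  }
  n_failed <- sum(is.na(samples))
  if (n_failed > 0.05 * n_reps) {
    warning("bootstrap_ricco(): ", n_failed, " of ", n_reps,
            " replicates had degenerate refits")
  }
  qs <- stats::quantile(samples, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
  structure(list(n_reps = n_reps, samples = samples,
                 lo_p5 = qs[1], hi_p95 = qs[2],
                 point = pick(point_fit), point_fit = point_fit,
                 statistic = statistic, n_failed = n_failed),
            class = "bootstrap_interval")
}

#' @export
print.bootstrap_interval <- function(x, ...) {
  cat(sprintf("Bootstrap of %s: point %.4g, 5-95%% interval [%.4g, %.4g]",
              x$statistic, x$point, x$lo_p5, x$hi_p95),
      sprintf("(%d reps, %d failed)\n", x$n_reps, x$n_failed))
  invisible(x)
}

#' Number of cones within a retinal area
#'
#' Multiplies the area by the angular cone density and rounds to the nearest
#' integer; exact halves round away from zero (not banker's rounding).
#'
#' @param area_arcmin2 Area in arcmin^2 (> 0).
#' @param density_cones_per_arcmin2 Angular cone density (> 0).
#' @return Integer cone count.
#' @export
cones_within_area <- function(area_arcmin2, density_cones_per_arcmin2) {
  if (any(area_arcmin2 <= 0) || any(density_cones_per_arcmin2 <= 0)) {
    stop("cones_within_area(): arguments must be positive")
  }
  x <- area_arcmin2 * density_cones_per_arcmin2
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Align per-subject summation curves and average them
#'
#' Each curve is shifted vertically so that its mean log energy matches the
#' grand mean across curves (removing absolute-sensitivity differences);
#' the pointwise mean is returned together with a +/- 2 SD band.
#'
#' @param curves List of `"summation_curve"` objects on identical area
#'   grids.
#' @return A `"summation_curve"` with extra columns `sd`, `lo_2sd`,
#'   `hi_2sd`, and an attribute `shifts` (the per-curve vertical offsets
#'   applied).
#' @export
align_and_average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  grid <- curves[[1]]$log10_area
  for (cv in curves) {
    if (length(cv$log10_area) != length(grid) ||
        any(abs(cv$log10_area - grid) > 1e-9)) {
      stop("align_and_average_curves(): curves must share one area grid")
    }
  }
  mat <- vapply(curves, function(cv) cv$log10_energy,
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  grand <- mean(mat)
  shifts <- grand - colMeans(mat)
  aligned <- sweep(mat, 2, shifts, `+`)
  avg <- rowMeans(aligned)
  sdv <- if (ncol(aligned) > 1) apply(aligned, 1, stats::sd) else
    rep(0, length(grid))
  out <- summation_curve(grid, avg, condition = "average")
  out$sd <- sdv
  out$lo_2sd <- avg - 2 * sdv
  out$hi_2sd <- avg + 2 * sdv
  attr(out, "shifts") <- shifts
  out
}
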