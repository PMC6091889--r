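# Trial-table I/O, configuration and end-to-end condition runs.

.trial_columns <- c("size_id", "intensity", "response",
                    "fx1", "fy1", "fx2", "fy2", "fx3", "fy3", "valid")

#' Load a trial table from CSV
#'
#' Validates the trial schema: `size_id,intensity,response` are required;
#' the six per-frame delivery coordinates (`fx1 ... fy3`, arcmin, image
#' convention) and `valid` are optional.  Additional columns (e.g.
#' `diameter_arcmin`) are carried through.  Invalid rows are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return Data frame of validated trial records; missing `valid` defaults
#'   to `TRUE`.
#' @export
load_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("size_id", "intensity", "response")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("load_trials(): missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(df$intensity) | df$intensity < 0 |
                 df$intensity > 1 | !(df$response %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("load_trials(): invalid intensity/response on data line(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  has_pos <- all(c("fx1", "fy1", "fx2", "fy2", "fx3", "fy3") %in% names(df))
  if (!has_pos) {
    part <- intersect(c("fx1", "fy1", "fx2", "fy2", "fx3", "fy3"),
                      names(df))
    if (length(part) > 0) {
      stop("load_trials(): partial frame-position columns: ",
           paste(part, collapse = ", "),
           " (need all six of fx1..fy3 or none)")
    }
  }
  if (is.null(df$valid)) df$valid <- TRUE
  df$valid <- as.logical(df$valid)
  df
}

#' Write a trial table to CSV
#'
#' @param trials Data frame of trial records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

# Small deterministic FNV-1a hash of a serialized object, for provenance.
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Configuration for an end-to-end condition run
#'
#' @param condition One of `"stabilized_AO"`, `"unstabilized_AO"`,
#'   `"natural_optics"`; chooses the optics defaults (diffraction-limited
#'   8-mm pupil for the AO conditions, typical aberrations over 3 mm for
#'   natural optics).
#' @param seed Integer master seed.
#' @param scale `"reduced"` or `"full"` observer scale.
#' @param calibration See [default_calibration()].
#' @param run_observer Also run the computational-observer model path
#'   (slow); default `FALSE`.
#' @param kernel_sigmas Bracketing kernel sigmas for the model path.
#' @param observer Ground-truth observer used when data are synthesized.
#' @param n_boot Bootstrap replicates (default 500).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(condition = c("stabilized_AO", "unstabilized_AO",
                                     "natural_optics"),
                       seed = 1, scale = c("reduced", "full"),
                       calibration = default_calibration(),
                       run_observer = FALSE, kernel_sigmas = c(1, 2),
                       observer = ground_truth_observer(),
                       n_boot = 500) {
  condition <- match.arg(condition)
  scale <- match.arg(scale)
  structure(list(condition = condition, seed = seed, scale = scale,
                 calibration = calibration, run_observer = run_observer,
                 kernel_sigmas = kernel_sigmas, observer = observer,
                 n_boot = n_boot),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `observer` and
#' `calibration` may be nested mappings.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("condition", "seed", "scale",
                                  "run_observer", "kernel_sigmas",
                                  "n_boot"))]
  if (!is.null(y$calibration)) {
    args$calibration <- do.call(default_calibration, y$calibration)
  }
  if (!is.null(y$observer)) {
    args$observer <- do.call(ground_truth_observer, y$observer)
  }
  do.call(run_config, args)
}

#' Run one experimental condition end to end
#'
#' Data path: a synthetic session is generated (or a supplied trial table
#' used), psychometric functions fitted per size, the summation curve
#' built, the two-segment regression fitted and bootstrapped.  Model path
#' (optional): observer summation curves for the bracketing kernels are
#' simulated and the interpolation fit computed against the data curve.
#' The result embeds the seed and a configuration hash for provenance.
#'
#' @param config A `"run_config"`.
#' @param trials Optional trial table (as from [load_trials()]); when
#'   `NULL`, a session is synthesized from `config$observer`.
#' @param out_dir Optional directory; when given, writes `results.json`
#'   and `summation_curve.csv` there.
#' @return List with `condition`, `ricco`, `bootstrap`, `curve`, `trials`,
#'   optionally `interpolation`, plus `seed` and `config_hash`.
#' @export
run_condition <- function(config, trials = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(trials)) {
    trials <- simulate_session(config$observer,
                               calibration = config$calibration,
                               seed = config$seed)
  }
  if (!is.null(trials$valid)) trials <- trials[as.logical(trials$valid), ]
  if (is.null(trials$diameter_arcmin)) {
    stop("run_condition(): trials need a diameter_arcmin column")
  }
  sizes <- sort(unique(trials$diameter_arcmin))
  fits <- lapply(sizes, function(d) {
    g <- trials[trials$diameter_arcmin == d, ]
    fit_yes_no_psychometric(g$intensity, g$response, log10_intensity = TRUE)
  })
  th <- data.frame(diameter_arcmin = sizes,
                   threshold_intensity = vapply(fits, `[[`, numeric(1),
                                                "threshold_78"))
  curve <- build_summation_curve(th, config$calibration,
                                 condition = config$condition)
  two_seg <- fit_two_segment(curve)
  boot <- bootstrap_ricco(trials, config$calibration,
                          n_reps = config$n_boot,
                          seed = config$seed + 1L)
  result <- list(condition = config$condition, seed = config$seed,
                 config_hash = .config_hash(unclass(config)),
                 ricco = two_seg, bootstrap = boot, curve = curve,
                 trials = trials, psychometric_fits = fits)
  if (isTRUE(config$run_observer)) {
    psf <- if (config$condition == "natural_optics") {
      z <- typical_aberrations()
      psf_from_zernike(z$osa_coeffs_microns, z$pupil_mm, z$wavelength_nm)
    } else {
      diffraction_limited_psf()
    }
    cfg <- observer_config(config$scale)
    t1 <- simulate_summation_curve(psf = psf,
                                   kernel_sigma = config$kernel_sigmas[1],
                                   config = cfg, seed = config$seed + 2L)
    t2 <- simulate_summation_curve(psf = psf,
                                   kernel_sigma = config$kernel_sigmas[2],
                                   config = cfg, seed = config$seed + 3L)
    result$interpolation <- interpolate_and_fit(t1, t2, curve,
                                                sigma_pair =
                                                  config$kernel_sigmas)
    result$model_curves <- list(T1 = t1, T2 = t2)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    res_json <- list(
      condition = result$condition,
      seed = result$seed,
      config_hash = result$config_hash,
      ricco_area_arcmin2 = two_seg$ricco_area_arcmin2,
      ricco_diameter_arcmin = two_seg$ricco_diameter_arcmin,
      second_slope = two_seg$second_slope,
      flat_level = two_seg$flat_level,
      ci5 = boot$lo_p5, ci95 = boot$hi_p95,
      n_valid_trials = nrow(trials))
    if (!is.null(result$interpolation)) {
      res_json$alpha <- result$interpolation$alpha
      res_json$sigma_interp <- result$interpolation$sigma_interp
      res_json$beta <- as.list(result$interpolation$beta)
    }
    jsonlite::write_json(res_json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(curve),
                     file.path(out_dir, "summation_curve.csv"),
                     row.names = FALSE)
  }
  result
}

#' Joint two-condition kernel fit
#'
#' Fits the interpolated kernel with a single `alpha` shared across
#' conditions and one vertical shift per condition.
#'
#' @param T1,T2 Bracketing model curves.
#' @param curves List of experimental `"summation_curve"`s (one per
#'   condition).
#' @param sigma_pair Bracketing sigmas.
#' @return An `"interpolation_fit"` with one `alpha` and one `beta` per
#'   condition.
#' @export
fit_kernel_joint <- function(T1, T2, curves, sigma_pair = c(1, 2)) {
  interpolate_and_fit(T1, T2, curves, sigma_pair = sigma_pair)
}
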