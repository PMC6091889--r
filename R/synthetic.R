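# Ground-truth-known generators for every pipeline stage: psychophysical
# sessions driven by adaptive staircases, fixational eye-motion delivery
# traces, and shifted noisy image pairs for the registration stage.

#' Ground-truth summation observer
#'
#' Embodies the two-segment summation model for data generation: log
#' threshold energy is flat up to the summation area and rises with the
#' stated slope beyond it; detection probability around the threshold
#' follows a logistic in log10 intensity.
#'
#' @param flat_level Log10 threshold energy on the flat branch
#'   (cd/m^2 * arcmin^2 * s units).
#' @param ricco_area_arcmin2 Summation area (breakpoint).
#' @param second_slope Slope of the second branch (0 < s < 1 typical).
#' @param psychometric_slope Logistic slope per log10-intensity unit
#'   (default 22; steep, so that psychometric fitting rather than response
#'   noise dominates recovery error).
#' @param guess,lapse Asymptotes of the generated responses.
#' @return Object of class `"ground_truth_observer"`.
#' @export
ground_truth_observer <- function(flat_level = 0.95,
                                  ricco_area_arcmin2 = disk_area(2.41),
                                  second_slope = 0.59,
                                  psychometric_slope = 22,
                                  guess = 0.03, lapse = 0.02) {
  stopifnot(ricco_area_arcmin2 > 0, psychometric_slope > 0)
  structure(list(flat_level = flat_level,
                 ricco_area_arcmin2 = ricco_area_arcmin2,
                 second_slope = second_slope,
                 psychometric_slope = psychometric_slope,
                 guess = guess, lapse = lapse),
            class = "ground_truth_observer")
}

#' Threshold-energy function of a ground-truth observer
#'
#' @param obs A `"ground_truth_observer"`.
#' @return Function mapping stimulus area (arcmin^2) to log10 threshold
#'   energy: flat below the breakpoint, slope `second_slope` above it.
#' @export
make_threshold_function <- function(obs) {
  stopifnot(inherits(obs, "ground_truth_observer"))
  force(obs)
  function(area_arcmin2) {
    la <- log10(area_arcmin2)
    lb <- log10(obs$ricco_area_arcmin2)
    obs$flat_level + obs$second_slope * pmax(la - lb, 0)
  }
}

#' Default intensity calibration
#'
#' Linear 8-bit intensity command mapping to luminance, with the stimulus
#' duration used to convert threshold intensity to threshold energy.
#'
#' @param max_luminance_cd_m2 Luminance at intensity 1 (default 828).
#' @param duration_s Stimulus duration (default 0.125 s).
#' @return Calibration list.
#' @export
default_calibration <- function(max_luminance_cd_m2 = 828,
                                duration_s = 0.125) {
  list(max_luminance_cd_m2 = max_luminance_cd_m2, duration_s = duration_s)
}

#' Simulate a staircase-driven psychophysical session
#'
#' For each stimulus size, `n_blocks` adaptive yes-no staircases of
#' `n_per_staircase` trials are run against the ground-truth observer: the
#' detection probability is a logistic in log10 intensity whose 78% point
#' sits at the intensity implied by the observer's threshold-energy
#' function and the calibration.
#'
#' @param obs A `"ground_truth_observer"`.
#' @param sizes Stimulus diameters in arcmin (default the 10 psychophysical
#'   diameters).
#' @param n_blocks Staircases per size (default 3, i.e. 60 trials/size).
#' @param n_per_staircase Trials per staircase (default 20).
#' @param calibration See [default_calibration()].
#' @param seed Integer seed; the session is a pure function of it.
#' @return Data frame of trials: `size_id`, `diameter_arcmin`, `block`,
#'   `trial`, `intensity`, `response`, `valid`.
#' @export
simulate_session <- function(obs, sizes = default_stimulus_diameters(),
                             n_blocks = 3, n_per_staircase = 20,
                             calibration = default_calibration(),
                             seed = 1) {
  stopifnot(inherits(obs, "ground_truth_observer"), all(sizes > 0))
  if (is.null(calibration$max_luminance_cd_m2)) {
    stop("simulate_session(): calibration missing max_luminance_cd_m2")
  }
  thr_fun <- make_threshold_function(obs)
  rows <- list()
  for (s in seq_along(sizes)) {
    area <- disk_area(sizes[s])
    e_thr <- 10^thr_fun(area)
    lum_thr <- e_thr / (area * calibration$duration_s)
    i_thr <- lum_thr / calibration$max_luminance_cd_m2
    if (i_thr <= 0 || i_thr > 1) {
      stop(sprintf(paste0("simulate_session(): threshold intensity %.3g for ",
                          "diameter %.3g arcmin is outside (0, 1]; adjust ",
                          "flat_level or calibration"), i_thr, sizes[s]))
    }
    # logistic in log10 intensity whose value at i_thr is 0.78
    k0 <- log((1 - obs$guess - obs$lapse) / (0.78 - obs$guess) - 1)
    alpha <- log10(i_thr) + k0 / obs$psychometric_slope
    responder <- function(intensity) {
      psychometric_fun(log10(intensity), alpha, obs$psychometric_slope,
                       obs$guess, obs$lapse)
    }
    for (b in seq_len(n_blocks)) {
      st <- run_staircase(responder, n_trials = n_per_staircase,
                          slope = obs$psychometric_slope,
                          guess = obs$guess, lapse = obs$lapse,
                          seed = (as.numeric(seed) * 10000 + s * 100 + b) %%
                            2147483647)
      rows[[length(rows) + 1]] <- data.frame(
        size_id = paste0("size", s), diameter_arcmin = sizes[s],
        block = b, trial = st$trial, intensity = st$intensity,
        response = st$response, valid = TRUE)
    }
  }
  do.call(rbind, rows)
}

#' Eye-motion generator parameters
#'
#' Brownian drift plus compound-Poisson microsaccades between stimulus
#' frames (1/16 s apart), with small tracking-error jitter in stabilized
#' mode.  The default presets are calibrated so that the median three-frame
#' travel is about 0.58 arcmin (stabilized) and 1.79 arcmin (unstabilized),
#' and the unstabilized between-trial delivery scatter is about 5.1 arcmin
#' per axis.
#'
#' @param drift_diffusion_arcmin2_per_s Per-axis displacement variance rate
#'   of the drift (arcmin^2/s).
#' @param microsaccade_rate_per_s Microsaccade rate.
#' @param microsaccade_amp_arcmin Mean microsaccade amplitude.
#' @param tracking_jitter_arcmin Per-axis SD of stabilized delivery error.
#' @param fixation_scatter_arcmin Per-axis SD of the trial starting
#'   position (unstabilized only).
#' @param frame_interval_s Frame interval (default 1/16 s).
#' @return Parameter list of class `"eye_motion_params"`.
#' @export
eye_motion_params <- function(drift_diffusion_arcmin2_per_s = 8.45,
                              microsaccade_rate_per_s = 0.25,
                              microsaccade_amp_arcmin = 6,
                              tracking_jitter_arcmin = 0.172,
                              fixation_scatter_arcmin = 5.08,
                              frame_interval_s = 1 / 16) {
  p <- list(drift_diffusion_arcmin2_per_s = drift_diffusion_arcmin2_per_s,
            microsaccade_rate_per_s = microsaccade_rate_per_s,
            microsaccade_amp_arcmin = microsaccade_amp_arcmin,
            tracking_jitter_arcmin = tracking_jitter_arcmin,
            fixation_scatter_arcmin = fixation_scatter_arcmin,
            frame_interval_s = frame_interval_s)
  if (any(unlist(p) < 0)) stop("eye_motion_params(): negative parameter")
  structure(p, class = "eye_motion_params")
}

#' Simulate three-frame delivery traces
#'
#' Unstabilized mode: the trial starting position is drawn from the
#' fixation scatter, and the two inter-frame displacements are Brownian
#' drift steps plus a Poisson number of microsaccade jumps (exponential
#' amplitude, uniform direction).  Stabilized mode: the three positions are
#' independent tracking-error jitter around the target.
#'
#' @param params An `"eye_motion_params"` list.
#' @param n_trials Number of traces.
#' @param stabilized Logical.
#' @param seed Integer seed.
#' @return Data frame with `trial_id`, `fx1 ... fy3`, `quality_ok`.
#' @export
simulate_fixational_trajectories <- function(params = eye_motion_params(),
                                             n_trials = 500,
                                             stabilized = FALSE,
                                             seed = 1) {
  stopifnot(inherits(params, "eye_motion_params"), n_trials >= 1)
  set.seed(seed)
  if (stabilized) {
    sj <- params$tracking_jitter_arcmin
    fx <- matrix(stats::rnorm(3 * n_trials, 0, sj), n_trials, 3)
    fy <- matrix(stats::rnorm(3 * n_trials, 0, sj), n_trials, 3)
  } else {
    sd_step <- sqrt(params$drift_diffusion_arcmin2_per_s *
                      params$frame_interval_s)
    start_x <- stats::rnorm(n_trials, 0, params$fixation_scatter_arcmin)
    start_y <- stats::rnorm(n_trials, 0, params$fixation_scatter_arcmin)
    fx <- matrix(0, n_trials, 3); fy <- matrix(0, n_trials, 3)
    fx[, 1] <- start_x; fy[, 1] <- start_y
    for (k in 2:3) {
      dx <- stats::rnorm(n_trials, 0, sd_step)
      dy <- stats::rnorm(n_trials, 0, sd_step)
      n_ms <- stats::rpois(n_trials,
                           params$microsaccade_rate_per_s *
                             params$frame_interval_s)
      has <- which(n_ms > 0)
      for (i in has) {
        amp <- stats::rexp(n_ms[i], 1 / params$microsaccade_amp_arcmin)
        ang <- stats::runif(n_ms[i], 0, 2 * pi)
        dx[i] <- dx[i] + sum(amp * cos(ang))
        dy[i] <- dy[i] + sum(amp * sin(ang))
      }
      fx[, k] <- fx[, k - 1] + dx
      fy[, k] <- fy[, k - 1] + dy
    }
  }
  data.frame(trial_id = seq_len(n_trials),
             fx1 = fx[, 1], fy1 = fy[, 1], fx2 = fx[, 2], fy2 = fy[, 2],
             fx3 = fx[, 3], fy3 = fy[, 3], quality_ok = TRUE)
}

#' Generate a shifted noisy image pair
#'
#' The base texture is a smoothed Gaussian random field; the second image
#' is the first shifted by an exact (possibly subpixel) amount via a
#' Fourier phase ramp, and independent Gaussian noise is added to both.
#'
#' @param base_texture_seed Integer seed for the texture and noise.
#' @param shift_px Numeric `c(dy, dx)` shift of image B relative to A in
#'   pixels (row shift first, matching [register_pair_dft()] output).
#' @param noise_sd Noise SD relative to the texture SD of 1 (default 0.05,
#'   i.e. SNR 20).
#' @param size Image side length in pixels (default 128).
#' @param smooth_px Gaussian smoothing scale of the texture (default 3).
#' @return List with matrices `A` and `B`.
#' @export
make_shifted_image_pair <- function(base_texture_seed = 1,
                                    shift_px = c(0, 0), noise_sd = 0.05,
                                    size = 128, smooth_px = 3) {
  if (max(abs(shift_px)) >= size / 4) {
    stop("make_shifted_image_pair(): |shift| must be < size/4")
  }
  set.seed(base_texture_seed)
  base <- matrix(stats::rnorm(size * size), size, size)
  f <- .fft_freqs(size)
  # isotropic Gaussian low-pass in the Fourier domain
  g <- exp(-2 * pi^2 * smooth_px^2 * outer(f^2, f^2, `+`) / size^2)
  fb <- stats::fft(base) * g
  A <- Re(stats::fft(fb, inverse = TRUE)) / size^2
  A <- (A - mean(A)) / stats::sd(A)
  ramp <- exp(-2i * pi * (outer(f * shift_px[1], rep(1, size)) +
                            outer(rep(1, size), f * shift_px[2])) / size)
  B <- Re(stats::fft(stats::fft(A) * ramp, inverse = TRUE)) / size^2
  list(A = A + stats::rnorm(size * size, 0, noise_sd),
       B = B + stats::rnorm(size * size, 0, noise_sd))
}
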