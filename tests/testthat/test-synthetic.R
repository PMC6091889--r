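test_that("threshold function is continuous with the stated branches", {
  obs <- ground_truth_observer(flat_level = -1,
                               ricco_area_arcmin2 = 4.56,
                               second_slope = 0.59)
  f <- make_threshold_function(obs)
  eps <- 1e-9
  expect_equal(f(4.56 - eps), f(4.56 + eps), tolerance = 1e-6)
  expect_equal(f(4.56 * 10), -1 + 0.59)
  expect_equal(f(0.1), -1)
  # s = 1 limiting case: constant threshold intensity beyond the knee
  obs1 <- ground_truth_observer(flat_level = -1, ricco_area_arcmin2 = 1,
                                second_slope = 1)
  f1 <- make_threshold_function(obs1)
  areas <- c(2, 5, 20)
  expect_equal(10^f1(areas) / areas, rep(10^-1, 3))
})

test_that("sessions produce 60 reproducible trials per size", {
  obs <- ground_truth_observer()
  ses <- simulate_session(obs, seed = 4)
  expect_equal(nrow(ses), 600)
  expect_true(all(table(ses$size_id) == 60))
  ses2 <- simulate_session(obs, seed = 4)
  expect_identical(ses, ses2)
  expect_error(simulate_session(obs, calibration = list()), "calibration")
})

test_that("detection rate at the planted threshold approaches 78%", {
  obs <- ground_truth_observer()
  area <- disk_area(1.16)
  i_thr <- 10^make_threshold_function(obs)(area) / (area * 0.125 * 828)
  k0 <- log((1 - 0.03 - 0.02) / (0.78 - 0.03) - 1)
  alpha <- log10(i_thr) + k0 / obs$psychometric_slope
  set.seed(19)
  p <- psychometric_fun(log10(i_thr), alpha, obs$psychometric_slope,
                        0.03, 0.02)
  hits <- rbinom(1, 5000, p)
  expect_equal(hits / 5000, 0.78, tolerance = 3 * sqrt(0.78 * 0.22 / 5000))
})

test_that("trajectory generators honour degenerate and drift-only regimes", {
  # all noise sources off: zero travel
  p0 <- eye_motion_params(drift_diffusion_arcmin2_per_s = 0,
                          microsaccade_rate_per_s = 0,
                          tracking_jitter_arcmin = 0,
                          fixation_scatter_arcmin = 0)
  z <- simulate_fixational_trajectories(p0, 100, stabilized = FALSE,
                                        seed = 1)
  expect_equal(max(intratrial_travel_all(z)), 0)
  zs <- simulate_fixational_trajectories(p0, 100, stabilized = TRUE,
                                         seed = 1)
  expect_equal(max(intratrial_travel_all(zs)), 0)
  # drift only: median travel matches a large Monte-Carlo oracle within 3%
  pd <- eye_motion_params(drift_diffusion_arcmin2_per_s = 5,
                          microsaccade_rate_per_s = 0,
                          fixation_scatter_arcmin = 0)
  tr <- simulate_fixational_trajectories(pd, 20000, stabilized = FALSE,
                                         seed = 2)
  med <- median(intratrial_travel_all(tr))
  set.seed(99)  # independent oracle: sum of two 2-D Gaussian step lengths
  sd_step <- sqrt(5 / 16)
  n <- 1e5
  oracle <- median(sqrt(rnorm(n, 0, sd_step)^2 + rnorm(n, 0, sd_step)^2) +
                     sqrt(rnorm(n, 0, sd_step)^2 + rnorm(n, 0, sd_step)^2))
  expect_equal(med, oracle, tolerance = 0.03 * oracle)
  # determinism
  a <- simulate_fixational_trajectories(n_trials = 50, seed = 7)
  b <- simulate_fixational_trajectories(n_trials = 50, seed = 7)
  expect_identical(a, b)
})

test_that("calibrated presets reproduce the two travel medians", {
  st <- simulate_fixational_trajectories(n_trials = 500, stabilized = TRUE,
                                         seed = 3)
  un <- simulate_fixational_trajectories(n_trials = 500, stabilized = FALSE,
                                         seed = 3)
  expect_equal(median(intratrial_travel_all(st)), 0.58, tolerance = 0.15)
  expect_equal(median(intratrial_travel_all(un)), 1.79, tolerance = 0.15)
})

test_that("shifted image pairs are exact and reproducible", {
  p0 <- make_shifted_image_pair(5, shift_px = c(0, 0), noise_sd = 0)
  expect_equal(p0$A, p0$B, tolerance = 1e-12)
  p1 <- make_shifted_image_pair(5, shift_px = c(3.7, -1.2), noise_sd = 0.05)
  p2 <- make_shifted_image_pair(5, shift_px = c(3.7, -1.2), noise_sd = 0.05)
  expect_identical(p1, p2)
  r <- register_pair_dft(p1$A, p1$B, window = FALSE)
  expect_lt(abs(r$dy_px - 3.7), 0.05)
  expect_lt(abs(r$dx_px + 1.2), 0.05)
  expect_error(make_shifted_image_pair(1, shift_px = c(40, 0), size = 128),
               "size/4")
})
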