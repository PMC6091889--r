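test_that("summation curves follow the energy convention", {
  cal <- quick_calibration()
  d <- default_stimulus_diameters()
  # constant threshold intensity: log energy rises with slope 1 in log area
  th <- data.frame(diameter_arcmin = d, threshold_intensity = 0.1)
  cur <- build_summation_curve(th, cal)
  expect_equal(nrow(cur), 10)
  slopes <- diff(cur$log10_energy) / diff(cur$log10_area)
  expect_equal(slopes, rep(1, 9), tolerance = 1e-9)
  # constant threshold energy: flat curve
  areas <- disk_area(d)
  th2 <- data.frame(diameter_arcmin = d,
                    threshold_intensity = 0.5 / areas)
  cur2 <- build_summation_curve(th2, cal)
  expect_equal(diff(cur2$log10_energy), rep(0, 9), tolerance = 1e-9)
  expect_error(build_summation_curve(th, list()), "calibration")
})

test_that("two-segment fit recovers exact model parameters", {
  tf <- make_threshold_function(ground_truth_observer(
    flat_level = -1, ricco_area_arcmin2 = 4.56, second_slope = 0.59))
  la <- log10(c(0.2, 0.5, 1, 2, 4.56, 8, 20, 67))
  fit <- fit_two_segment(summation_curve(la, tf(10^la)))
  expect_equal(fit$flat_level, -1, tolerance = 1e-6)
  expect_equal(fit$ricco_area_arcmin2, 4.56, tolerance = 1e-6)
  expect_equal(fit$second_slope, 0.59, tolerance = 1e-6)
  expect_false(fit$boundary)
  expect_equal(fit$ricco_diameter_arcmin,
               2 * sqrt(fit$ricco_area_arcmin2 / pi))
})

test_that("two-segment fit is scale-equivariant and flags flat data", {
  cur <- make_noisy_curve(31)
  fit <- fit_two_segment(cur)
  shifted <- summation_curve(cur$log10_area, cur$log10_energy + 2.5)
  fit2 <- fit_two_segment(shifted)
  expect_equal(fit2$flat_level, fit$flat_level + 2.5, tolerance = 1e-6)
  expect_equal(fit2$breakpoint_log_area, fit$breakpoint_log_area,
               tolerance = 1e-6)
  expect_equal(fit2$second_slope, fit$second_slope, tolerance = 1e-6)
  flat <- summation_curve(cur$log10_area, rep(-1, nrow(cur)))
  expect_true(fit_two_segment(flat)$boundary)
})

test_that("stratified bootstrap returns the requested replicates", {
  obs <- ground_truth_observer()
  ses <- simulate_session(obs, sizes = default_stimulus_diameters()[c(1, 3, 5, 7, 9)],
                          seed = 41)
  bt <- bootstrap_ricco(ses, quick_calibration(), n_reps = 50, seed = 2)
  expect_length(bt$samples, 50)
  expect_lte(bt$lo_p5, bt$hi_p95)
  expect_lte(bt$n_failed, 5)
})

test_that("cone counts round half away from zero", {
  expect_identical(cones_within_area(10.4, 1), 10L)
  expect_identical(cones_within_area(4, 5.25), 21L)
  expect_identical(cones_within_area(1, 2.5), 3L)   # 2.5 -> 3, not 2
  expect_identical(cones_within_area(1, 3.5), 4L)
  expect_error(cones_within_area(-1, 1))
})

test_that("curve alignment removes constant offsets", {
  la <- log10(disk_area(default_stimulus_diameters()))
  base <- -1 + 0.5 * pmax(la - 0.5, 0)
  c1 <- summation_curve(la, base)
  c2 <- summation_curve(la, base + 0.8)
  c3 <- summation_curve(la, base - 0.3)
  avg <- align_and_average_curves(list(c1, c2, c3))
  expect_equal(avg$log10_energy, base + mean(c(0, 0.8, -0.3)),
               tolerance = 1e-9)
  expect_equal(avg$sd, rep(0, length(la)), tolerance = 1e-9)
  # identical curves: same curve out
  same <- align_and_average_curves(list(c1, c1))
  expect_equal(same$log10_energy, base)
  # two-point arithmetic example
  ca <- summation_curve(c(0, 1), c(0, 1))
  cb <- summation_curve(c(0, 1), c(2, 3))
  ab <- align_and_average_curves(list(ca, cb))
  expect_equal(ab$log10_energy, c(1, 2))
  expect_error(align_and_average_curves(list(
    ca, summation_curve(c(0, 2), c(0, 1)))), "grid")
})
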