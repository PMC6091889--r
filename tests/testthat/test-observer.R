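test_that("pooling weights form a Gaussian centred on the central cone", {
  m <- assign_cone_classes(build_hex_mosaic(fov_deg = 0.1), seed = 1)
  k <- pooling_kernel(m, 1.6)
  expect_equal(which.max(k$weights), m$central_cone)
  expect_true(all(k$weights > 0))
  # sigma -> 0 limit: pooled series equals the central cone's series
  k0 <- pooling_kernel(m, 1e-4)
  inst <- draw_response_instances(matrix(5, m$n_cones, 31), 10, seed = 2)
  pooled0 <- pool_with_kernel(inst, k0)
  central <- inst$counts[, (m$central_cone - 1) * 31 + seq_len(31)]
  expect_equal(pooled0, central, tolerance = 1e-6)
  # uniform weights: per-bin total count
  ku <- k; ku$weights <- rep(1, m$n_cones)
  tot <- pool_with_kernel(inst, ku)
  manual <- sapply(seq_len(31), function(b) {
    rowSums(inst$counts[, (seq_len(m$n_cones) - 1) * 31 + b])
  })
  expect_equal(tot, manual)
  # linearity in counts for a single response map
  a <- matrix(rpois(m$n_cones * 31, 5), m$n_cones, 31)
  b <- matrix(rpois(m$n_cones * 31, 5), m$n_cones, 31)
  expect_equal(pool_with_kernel(2 * a + b, k),
               2 * pool_with_kernel(a, k) + pool_with_kernel(b, k))
})

test_that("two-interval vectors have the documented geometry", {
  mos <- assign_cone_classes(build_hex_mosaic(), seed = 1)  # 635 cones
  means <- matrix(5, mos$n_cones, 31)
  s <- draw_response_instances(means, 4, seed = 1)
  n <- draw_response_instances(means, 4, seed = 2)
  tv <- assemble_two_interval_vectors(s$counts, n$counts, seed = 3)
  expect_equal(ncol(tv$x), 39370)            # 635 x 31 x 2
  expect_equal(as.numeric(table(tv$y)), c(2, 2))
  kp <- pooling_kernel(mos, 1.6)
  tvp <- assemble_two_interval_vectors(pool_with_kernel(s, kp),
                                       pool_with_kernel(n, kp), seed = 3)
  expect_equal(ncol(tvp$x), 62)              # 1 kernel x 31 x 2
  # balance is exact at any even n
  s2 <- draw_response_instances(matrix(3, 5, 31), 100, seed = 4)
  n2 <- draw_response_instances(matrix(3, 5, 31), 100, seed = 5)
  tv2 <- assemble_two_interval_vectors(s2$counts, n2$counts, seed = 6)
  expect_equal(as.numeric(table(tv2$y)), c(50, 50))
  expect_error(assemble_two_interval_vectors(s2$counts,
                                             n2$counts[1:10, ]), "unequal")
})

test_that("SVM decodes separable stimuli and is at chance for permuted labels", {
  m <- assign_cone_classes(build_hex_mosaic(fov_deg = 0.1), seed = 1)
  k <- pooling_kernel(m, 1.6)
  bg <- matrix(10, m$n_cones, 31)
  hot <- bg; hot[, 6:25] <- hot[, 6:25] + 12
  s <- pool_with_kernel(draw_response_instances(hot, 300, seed = 1), k)
  n <- pool_with_kernel(draw_response_instances(bg, 300, seed = 2), k)
  tv <- assemble_two_interval_vectors(s, n, seed = 3)
  expect_gte(cv_svm_performance(tv$x, tv$y, seed = 4), 0.99)
  # permutation control: destroying labels gives chance
  set.seed(5)
  yperm <- sample(tv$y)
  expect_lt(abs(cv_svm_performance(tv$x, yperm, seed = 6) - 0.5), 0.05)
  expect_error(cv_svm_performance(tv$x, factor(rep("a", nrow(tv$x)))),
               "single")
  # PCA path agrees on an easy problem
  expect_gte(cv_svm_performance(tv$x, tv$y, n_pca = 10, seed = 7), 0.99)
})

test_that("Weibull threshold extraction is self-consistent", {
  E <- 10^seq(-1, 1, length.out = 12)
  p <- 0.5 + 0.5 * (1 - exp(-(E / 1.7)^1.3))
  fit <- observer_threshold(E, p, n_trials = 500)
  truth <- 1.7 * log(2)^(1 / 1.3)
  expect_equal(fit$threshold_75, truth, tolerance = 0.03 * truth)
  # noisy draws from the same curve
  set.seed(8)
  p2 <- rbinom(length(E), 400, p) / 400
  fit2 <- observer_threshold(E, p2, n_trials = 400)
  expect_equal(fit2$threshold_75, truth, tolerance = 0.15 * truth)
  # monotone step data: threshold brackets the step
  ps <- c(0.5, 0.5, 0.5, 1, 1, 1)
  Es <- 10^seq(0, 2.5, length.out = 6)
  fs <- observer_threshold(Es, ps, n_trials = 100)
  expect_gt(fs$threshold_75, Es[3])
  expect_lt(fs$threshold_75, Es[4])
  expect_error(observer_threshold(E, rep(1, 12)), "below 75")
  expect_error(observer_threshold(E, rep(0.55, 12)), "reaches 75")
})

test_that("interpolation fit honours the endpoint and arithmetic identities", {
  la <- seq(-1, 2, length.out = 12)
  t1 <- summation_curve(la, -0.5 + 0.3 * pmax(la - 0.3, 0))
  t2 <- summation_curve(la, -0.2 + 0.5 * pmax(la - 0.8, 0))
  # alpha = 1: data equal to T1 + beta
  d1 <- summation_curve(la, t1$log10_energy + 1.3)
  f1 <- interpolate_and_fit(t1, t2, d1)
  expect_equal(f1$alpha, 1, tolerance = 1e-4)
  expect_equal(unname(f1$beta), 1.3, tolerance = 1e-6)
  expect_equal(f1$sigma_interp, 1, tolerance = 1e-3)
  # Eq.-2 arithmetic: alpha = 0.4 -> sigma 1.6 for the (1, 2) bracket
  mix <- summation_curve(la, 0.4 * t1$log10_energy +
                           0.6 * t2$log10_energy - 0.7)
  fm <- interpolate_and_fit(t1, t2, mix)
  expect_equal(fm$alpha, 0.4, tolerance = 1e-4)
  expect_equal(fm$sigma_interp, 1.6, tolerance = 1e-3)
  expect_lt(fm$rmse, 1e-8)
})

test_that("interpolation matches a 400x400 grid-search oracle", {
  set.seed(13)
  la <- seq(-1, 2, length.out = 12)
  t1v <- -0.5 + 0.3 * pmax(la - 0.3, 0)
  t2v <- -0.2 + 0.5 * pmax(la - 0.8, 0)
  y <- 0.35 * t1v + 0.65 * t2v + 0.4 + rnorm(12, 0, 0.05)
  fit <- interpolate_and_fit(summation_curve(la, t1v),
                             summation_curve(la, t2v),
                             summation_curve(la, y))
  oracle <- oracle_interpolation_grid(t1v, t2v, y)
  expect_lte(fit$rmse, oracle$rmse + 1e-9)
  expect_lt(abs(fit$alpha - oracle$alpha), 1.5 / 400)
})

test_that("joint fits share alpha but keep per-condition shifts", {
  la <- seq(-1, 2, length.out = 12)
  t1 <- summation_curve(la, -0.5 + 0.3 * pmax(la - 0.3, 0))
  t2 <- summation_curve(la, -0.2 + 0.5 * pmax(la - 0.8, 0))
  mixv <- 0.3 * t1$log10_energy + 0.7 * t2$log10_energy
  d1 <- summation_curve(la, mixv + 2.0, condition = "corrected")
  d2 <- summation_curve(la, mixv + 2.4, condition = "natural")
  fj <- fit_kernel_joint(t1, t2, list(d1, d2))
  expect_length(fj$alpha, 1)
  expect_length(fj$beta, 2)
  expect_equal(unname(fj$beta), c(2.0, 2.4), tolerance = 1e-6)
  expect_equal(names(fj$beta), c("corrected", "natural"))
  expect_equal(fj$alpha, 0.3, tolerance = 1e-4)
})
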