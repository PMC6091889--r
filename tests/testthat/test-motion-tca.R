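test_that("delivery filtering applies the closed square window", {
  tr <- data.frame(trial_id = 1:4,
                   fx1 = c(0, 0, 0, 2.375), fy1 = c(0, 0, 0, 0),
                   fx2 = c(0.1, 0, 0, 0),   fy2 = c(0, 0, 0, 0),
                   fx3 = c(0, 4, 0, 0),     fy3 = c(0, 0, 0, 0))
  # trial 2 has frame 3 displaced 4 arcmin (> half-window 2.375): excluded;
  # trial 4 sits exactly on the boundary of the closed window: included
  kept <- filter_valid_deliveries(tr)
  expect_equal(kept$trial_id, c(1, 3, 4))
  # all traces at one point: all pass
  one <- data.frame(trial_id = 1:3, fx1 = 1, fy1 = 1, fx2 = 1, fy2 = 1,
                    fx3 = 1, fy3 = 1)
  expect_equal(nrow(filter_valid_deliveries(one)), 3)
  expect_error(filter_valid_deliveries(one[0, ]), "empty")
})

test_that("intratrial travel sums the two segment lengths", {
  expect_equal(intratrial_travel(rbind(c(0, 0), c(3, 4), c(3, 4))), 5)
  expect_equal(intratrial_travel(rbind(c(0, 0), c(1, 0), c(2, 0))), 2)
  expect_equal(intratrial_travel(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_error(intratrial_travel(rbind(c(0, 0), c(1, 1))), "3")
  # invariance under global translation and rotation
  p <- rbind(c(0.2, -0.3), c(1.1, 0.4), c(0.6, 1.9))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(intratrial_travel(p %*% R + 5), intratrial_travel(p))
  # vectorized version agrees
  tr <- data.frame(fx1 = p[1, 1], fy1 = p[1, 2], fx2 = p[2, 1],
                   fy2 = p[2, 2], fx3 = p[3, 1], fy3 = p[3, 2])
  expect_equal(intratrial_travel_all(tr), intratrial_travel(p))
})

test_that("delivery dispersion scalarizes per-axis standard deviations", {
  expect_equal(as.numeric(delivery_dispersion(rbind(c(1, 1), c(1, 1)))), 0)
  # points on the x-axis only: mean of (sd_x, 0) = sd_x / 2
  px <- cbind(c(-1, 0, 2, 4), 0)
  expect_equal(as.numeric(delivery_dispersion(px)), sd(px[, 1]) / 2)
  # isotropic Gaussian cloud, Monte Carlo
  set.seed(17)
  cloud <- matrix(rnorm(2e4), ncol = 2)
  expect_equal(as.numeric(delivery_dispersion(cloud)), 1, tolerance = 0.03)
  expect_error(delivery_dispersion(rbind(c(1, 2))), "2 positions")
})

test_that("DFT registration recovers integer and subpixel shifts", {
  pair0 <- make_shifted_image_pair(1, shift_px = c(0, 0), noise_sd = 0)
  r0 <- register_pair_dft(pair0$A, pair0$A)
  expect_equal(c(r0$dy_px, r0$dx_px), c(0, 0))
  expect_gt(r0$peak_corr, 0.99)
  # integer circular roll is recovered exactly
  A <- pair0$A
  B <- A[c((nrow(A) - 4):nrow(A), 1:(nrow(A) - 5)),
         c(4:ncol(A), 1:3)]  # rows +5, cols -3
  r <- register_pair_dft(A, B, window = FALSE)
  expect_equal(c(r$dy_px, r$dx_px), c(5, -3))
  # subpixel phase-ramp shifts within 0.05 px (periodic input: no window)
  pair <- make_shifted_image_pair(2, shift_px = c(2.30, -1.45),
                                  noise_sd = 0.05)
  rs <- register_pair_dft(pair$A, pair$B, window = FALSE)
  expect_lt(abs(rs$dy_px - 2.30), 0.05)
  expect_lt(abs(rs$dx_px + 1.45), 0.05)
  # antisymmetry of the two registration directions
  rb <- register_pair_dft(pair$B, pair$A, window = FALSE)
  expect_lt(abs(rs$dy_px + rb$dy_px), 0.05)
  expect_lt(abs(rs$dx_px + rb$dx_px), 0.05)
  expect_error(register_pair_dft(matrix(1, 8, 8), matrix(1, 8, 8)),
               "flat")
})

test_that("TCA combines sessions by median then mean", {
  const <- data.frame(dx_px = rep(1, 10), dy_px = rep(2, 10))
  expect_equal(tca_from_offsets(const, const), c(dx = 1, dy = 2))
  # a gross outlier frame does not move the median
  outl <- data.frame(dx_px = c(rep(1, 39), 50), dy_px = c(rep(1, 39), 50))
  expect_equal(tca_from_offsets(outl, outl), c(dx = 1, dy = 1))
  pre <- data.frame(dx_px = 0, dy_px = 0)
  post <- data.frame(dx_px = 2, dy_px = 2)
  expect_equal(tca_from_offsets(pre, post), c(dx = 1, dy = 1))
  # single-session form and list-of-offsets form
  expect_equal(tca_from_offsets(post), c(dx = 2, dy = 2))
  offs <- list(list(dx_px = 1, dy_px = 0), list(dx_px = 3, dy_px = 2),
               list(dx_px = 2, dy_px = 1))
  expect_equal(tca_from_offsets(offs), c(dx = 2, dy = 1))
  expect_error(tca_from_offsets(const[0, ]), "empty")
})
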