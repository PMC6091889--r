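# Shared fixtures and independent oracles used across test files.

# Noisy two-segment curve with known parameters.
make_noisy_curve <- function(seed, flat = -1, ricco_area = 4.56, s = 0.59,
                             noise = 0.03, n = 10) {
  set.seed(seed)
  la <- seq(log10(0.15), log10(67), length.out = n)
  y <- flat + s * pmax(la - log10(ricco_area), 0) + rnorm(n, 0, noise)
  summation_curve(la, y)
}

# Brute-force two-segment oracle: closed-form conditional least squares via
# lm() at each of n_cand breakpoint candidates; returns the minimum RSS.
oracle_two_segment_rss <- function(curve, n_cand = 1000) {
  x <- curve$log10_area; y <- curve$log10_energy
  bs <- seq(min(x), max(x), length.out = n_cand)
  best <- Inf
  for (b in bs) {
    h <- pmax(x - b, 0)
    fit <- if (all(h == 0)) lm(y ~ 1) else lm(y ~ h)
    rss <- sum(resid(fit)^2)
    if (rss < best) best <- rss
  }
  best
}

# Exhaustive grid MLE oracle for the logistic psychometric fit.
oracle_psychometric_grid <- function(intensity, response, guess = 0.03,
                                     lapse = 0.02, n_grid = 200) {
  alphas <- seq(min(intensity), max(intensity), length.out = n_grid)
  betas <- exp(seq(log(0.5), log(500), length.out = n_grid))
  best <- -Inf
  for (a in alphas) {
    for (b in betas) {
      p <- psychometric_fun(intensity, a, b, guess, lapse)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- sum(response * log(p) + (1 - response) * log(1 - p))
      if (ll > best) best <- ll
    }
  }
  best
}

# 2-D grid oracle for the (alpha, beta) interpolation fit (single
# condition): minimizes RMSE over a 400 x 400 grid.
oracle_interpolation_grid <- function(t1, t2, y, n_grid = 400) {
  alphas <- seq(0, 1, length.out = n_grid)
  bspan <- range(y) - rev(range(c(t1, t2)))
  betas <- seq(bspan[1] - 0.5, bspan[2] + 0.5, length.out = n_grid)
  best <- Inf; best_a <- NA
  for (a in alphas) {
    pred <- t1 * a + t2 * (1 - a)
    # vectorized over the beta grid
    mses <- vapply(betas, function(b) mean((y - pred - b)^2), numeric(1))
    i <- which.min(mses)
    if (mses[i] < best) { best <- mses[i]; best_a <- a }
  }
  list(rmse = sqrt(best), alpha = best_a)
}

quick_calibration <- function() default_calibration()
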