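# Yes-no psychometric fitting and an adaptive (QUEST-style) staircase.
#
# The psychometric model is a logistic with fixed guess and lapse rates:
#   psi(x) = gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha)))
# where x is the stimulus intensity, optionally log10-transformed.  A yes-no
# task without catch trials cannot identify the guess rate from data, so
# gamma and lambda are held at small fixed values and exposed as arguments.

#' Logistic psychometric function
#'
#' @param x Stimulus intensity (on the scale the fit was performed on).
#' @param alpha Location parameter.
#' @param beta Slope (> 0).
#' @param gamma Guess rate (lower asymptote).
#' @param lambda Lapse rate (1 - upper asymptote).
#' @return Detection probability.
#' @export
psychometric_fun <- function(x, alpha, beta, gamma = 0.03, lambda = 0.02) {
  gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha)))
}

# Negative log-likelihood on binomially aggregated data, plus gradient.
# par = c(alpha, log_beta).
.psy_negll <- function(par, x, k, n, gamma, lambda) {
  beta <- exp(par[2])
  p <- psychometric_fun(x, par[1], beta, gamma, lambda)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

.psy_negll_grad <- function(par, x, k, n, gamma, lambda) {
  beta <- exp(par[2])
  z <- beta * (x - par[1])
  s <- 1 / (1 + exp(-z))
  p <- gamma + (1 - gamma - lambda) * s
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  w <- (k / p - (n - k) / (1 - p)) * (1 - gamma - lambda) * s * (1 - s)
  # d z / d alpha = -beta; d z / d log_beta = z
  c(sum(w * beta), -sum(w * z))
}

#' Fit a yes-no psychometric function by maximum likelihood
#'
#' Fits the logistic model with fixed guess and lapse rates to trial-level
#' yes/no data.  The likelihood is maximized with BFGS from several
#' deterministic starting points (location starts at data quantiles crossed
#' with a coarse range of slopes); ties are broken by the best likelihood and
#' then the smallest `alpha`, so the fit is reproducible.
#'
#' @param intensity Numeric vector of stimulus intensities in `[0, 1]`.
#' @param response Binary vector (0/1 or logical) of detection responses.
#' @param guess,lapse Fixed asymptote parameters (defaults 0.03 and 0.02).
#' @param log10_intensity If `TRUE`, fit on `log10(intensity)`; thresholds
#'   are always reported back on the intensity scale.
#' @param criterion Detection probability defining the reported threshold
#'   (default 0.78).
#' @param start Optional `c(alpha, beta)` warm start (on the fitting scale);
#'   when supplied, only this start is used — intended for bootstrap refits.
#' @return Object of class `"psychometric_fit"`: list with `alpha`, `beta`,
#'   `gamma`, `lambda`, `loglik`, `threshold_78` (intensity at `criterion`),
#'   `log10_intensity`, `n_trials`.
#' @export
fit_yes_no_psychometric <- function(intensity, response, guess = 0.03,
                                    lapse = 0.02, log10_intensity = FALSE,
                                    criterion = 0.78, start = NULL) {
  response <- as.integer(response)
  stopifnot(length(intensity) == length(response),
            all(response %in% c(0L, 1L)))
  if (any(intensity <= 0) && log10_intensity) {
    stop("fit_yes_no_psychometric(): nonpositive intensity with log10 scale")
  }
  if (all(response == 1L) || all(response == 0L)) {
    stop("fit_yes_no_psychometric(): degenerate data (all responses ",
         if (all(response == 1L)) "'yes'" else "'no'",
         "); the threshold is not identified")
  }
  x_raw <- if (log10_intensity) log10(intensity) else intensity
  # aggregate to binomial counts per distinct level
  lev <- sort(unique(x_raw))
  if (length(lev) < 2) {
    stop("fit_yes_no_psychometric(): need >= 2 distinct intensities")
  }
  idx <- match(x_raw, lev)
  k <- as.numeric(tapply(response, idx, sum))
  n <- as.numeric(tabulate(idx, nbins = length(lev)))

  span <- max(diff(range(lev)), 1e-6)
  if (is.null(start)) {
    alpha0 <- unname(stats::quantile(x_raw, c(0.25, 0.5, 0.5, 0.75, 0.5)))
    beta0 <- c(2, 2, 8, 8, 32) / span
    starts <- cbind(alpha0, log(beta0))
  } else {
    starts <- matrix(c(start[1], log(start[2])), nrow = 1)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], .psy_negll, gr = .psy_negll_grad,
                   x = lev, k = k, n = n, gamma = guess, lambda = lapse,
                   method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("fit_yes_no_psychometric(): optimization failed")

  alpha <- unname(best$par[1])
  beta <- unname(exp(best$par[2]))
  out <- structure(list(
    alpha = alpha, beta = beta, gamma = guess, lambda = lapse,
    loglik = -best$value, log10_intensity = log10_intensity,
    criterion = criterion, n_trials = length(response),
    threshold_78 = NA_real_
  ), class = "psychometric_fit")
  out$threshold_78 <- threshold_at_criterion(out, criterion)
  out
}

#' Intensity at a criterion detection probability
#'
#' Analytic inverse of the fitted logistic.  The returned value is on the
#' intensity scale even when the fit was performed on log10 intensity.
#'
#' @param fit A `"psychometric_fit"` object.
#' @param p Criterion probability; must lie strictly between the asymptotes.
#' @return Intensity at which the fitted function equals `p`.
#' @export
threshold_at_criterion <- function(fit, p = 0.78) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (p <= fit$gamma || p >= 1 - fit$lambda) {
    stop("threshold_at_criterion(): criterion ", p,
         " lies outside the asymptotes (", fit$gamma, ", ",
         1 - fit$lambda, ")")
  }
  q <- (1 - fit$gamma - fit$lambda) / (p - fit$gamma) - 1
  x <- fit$alpha - log(q) / fit$beta
  if (isTRUE(fit$log10_intensity)) 10^x else x
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Yes-no psychometric fit (logistic",
      if (x$log10_intensity) "on log10 intensity" else "on intensity", ")\n")
  cat(sprintf("  alpha = %.4g  beta = %.4g  gamma = %.3g  lambda = %.3g\n",
              x$alpha, x$beta, x$gamma, x$lambda))
  cat(sprintf("  threshold (p = %.2f): %.4g   logLik = %.3f   n = %d\n",
              x$criterion, x$threshold_78, x$loglik, x$n_trials))
  invisible(x)
}

#' Run a QUEST-style adaptive yes-no staircase
#'
#' A Bayesian staircase over a fixed intensity grid.  The prior over the
#' threshold location is uniform on the (log-spaced) grid; after each trial
#' the posterior is updated with the logistic likelihood (fixed slope, guess
#' and lapse) and the next trial is placed at the posterior mode.
#'
#' @param observer Function mapping intensity to detection probability.
#' @param n_trials Number of trials (default 20).
#' @param grid Intensity placement grid (default 41 log-spaced values from
#'   1/255 to 1, emulating an 8-bit intensity ladder).
#' @param slope Assumed logistic slope per log10-intensity unit (default 10).
#' @param guess,lapse Assumed asymptotes.
#' @param seed Optional integer seed for the response draws.
#' @return Data frame with columns `trial`, `intensity`, `response` plus an
#'   attribute `posterior_mode` (final threshold estimate, intensity scale).
#' @export
run_staircase <- function(observer, n_trials = 20,
                          grid = 10^seq(log10(1 / 255), 0, length.out = 41),
                          slope = 10, guess = 0.03, lapse = 0.02,
                          seed = NULL) {
  stopifnot(is.function(observer), n_trials >= 1)
  if (length(grid) < 2 || any(grid <= 0)) {
    stop("run_staircase(): grid must contain >= 2 positive intensities")
  }
  if (!is.null(seed)) set.seed(seed)
  lg <- log10(sort(grid))
  log_post <- rep(0, length(lg))          # uniform prior over grid
  placed <- integer(n_trials)
  resp <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    i <- which.max(log_post)              # posterior mode placement
    placed[t] <- i
    p_true <- observer(10^lg[i])
    resp[t] <- stats::rbinom(1, 1, min(max(p_true, 0), 1))
    # likelihood of the response for every candidate threshold
    p_cand <- psychometric_fun(lg[i], lg, slope, guess, lapse)
    p_cand <- pmin(pmax(p_cand, 1e-9), 1 - 1e-9)
    log_post <- log_post +
      if (resp[t] == 1L) log(p_cand) else log(1 - p_cand)
    log_post <- log_post - max(log_post)
  }
  out <- data.frame(trial = seq_len(n_trials),
                    intensity = 10^lg[placed],
                    response = resp)
  attr(out, "posterior_mode") <- 10^lg[which.max(log_post)]
  out
}
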