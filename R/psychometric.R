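#' Scaled Weibull psychometric function
#'
#' Proportion correct as a function of stimulus level `x` (log2 channels):
#' \deqn{p(x) = \gamma + (1 - \gamma - \lambda)\,[1 - e^{-(x/\alpha)^\beta}]}
#' where `gamma` is the guess rate (floor), `lam` the lapse rate (the curve
#' saturates at `1 - lam`), and `alpha`, `beta` the Weibull scale and shape
#' on the log2-channel axis.
#'
#' @param params A list-like object with fields `alpha`, `beta`, `gamma`,
#'   `lam` (e.g. a [listener_params()] or a [fit_psychometric()] result).
#' @param x Stimulus level(s), log2 channels; must be >= 0.
#' @return Probability of a correct digit, same length as `x`; monotone
#'   non-decreasing in `x`, ranging over \[`gamma`, `1 - lam`\].
#' @export
predict_pcorrect <- function(params, x) {
  if (any(x < 0)) stop("`x` (log2 channels) must be >= 0", call. = FALSE)
  if (params$alpha <= 0 || params$beta <= 0)
    stop("Weibull scale and shape must be positive", call. = FALSE)
  F <- 1 - exp(-(x / params$alpha)^params$beta)
  params$gamma + (1 - params$gamma - params$lam) * F
}

#' Negative log-likelihood of per-level success counts
#'
#' Binomial when `eta = 0`; beta-binomial otherwise, parameterized so the
#' latent per-level success probability has mean `p(x)` and variance
#' `eta^2 p(1-p)`: shape parameters `a = p * nu`, `b = (1-p) * nu` with
#' `nu = 1/eta^2 - 1`. `eta -> 0` recovers the binomial exactly.
#'
#' @param params List-like with `alpha`, `beta`, `gamma`, `lam`, `eta`.
#' @param data Data frame with columns `x` (log2 channels), `k` (successes)
#'   and `n` (trials), one row per level.
#' @return The negative log-likelihood (lower is better).
#' @export
neg_log_likelihood <- function(params, data) {
  eta <- params$eta
  if (is.null(eta)) eta <- 0
  if (eta < 0 || eta >= 1)
    stop("`eta` must lie in [0, 1)", call. = FALSE)
  p <- predict_pcorrect(params, data$x)
  eps <- 1e-9
  p <- pmin(pmax(p, eps), 1 - eps)
  if (eta < 1e-8) {
    -sum(stats::dbinom(data$k, data$n, p, log = TRUE))
  } else {
    nu <- 1 / eta^2 - 1
    a <- p * nu
    b <- (1 - p) * nu
    ll <- lchoose(data$n, data$k) + lbeta(data$k + a, data$n - data$k + b) -
      lbeta(a, b)
    -sum(ll)
  }
}

#' Fitting options
#'
#' @param grid_alpha,grid_beta Number of grid points for the coarse
#'   initialization over (scale, shape).
#' @param n_starts Number of best grid points carried into local
#'   optimization.
#' @param lower,upper Box bounds on `(alpha, beta, gamma, lam, eta)`.
#' @param maxit Iteration cap per local optimization.
#' @return A list of options for [fit_psychometric()].
#' @export
fit_options <- function(grid_alpha = 12, grid_beta = 8, n_starts = 3,
                        lower = c(alpha = 0.01, beta = 0.1, gamma = 0,
                                  lam = 0, eta = 0),
                        upper = c(alpha = log2(48), beta = 20, gamma = 0.25,
                                  lam = 0.25, eta = 0.95),
                        maxit = 300) {
  list(grid_alpha = grid_alpha, grid_beta = grid_beta, n_starts = n_starts,
       lower = lower, upper = upper, maxit = maxit)
}

#' Fit the Weibull psychometric function by maximum likelihood
#'
#' Coarse grid search over (scale, shape) with nuisance parameters at small
#' defaults, followed by bounded (L-BFGS-B) local optimization over all
#' five parameters from the best grid points. Entirely deterministic given
#' the data and options. Degenerate data (all successes or all failures)
#' yield a flagged boundary fit rather than an error.
#'
#' @param data Per-level counts: a data frame with columns `x`, `k`, `n`
#'   (as produced by [aggregate_trials()]), or the object returned by
#'   [aggregate_trials()] itself. At least 4 levels with `n > 0`.
#' @param opts Options from [fit_options()].
#' @return An object of class `psychometric_fit`: `alpha`, `beta`, `gamma`,
#'   `lam`, `eta`, `nll`, `converged`, `degenerate`, plus derived
#'   `threshold` (channels at 50\% correct, `NA` if undefined),
#'   `threshold_defined` and `slope` (at the threshold point, per log2
#'   channel).
#' @export
fit_psychometric <- function(data, opts = fit_options()) {
  if (inherits(data, "psychometric_data")) data <- data$data
  stopifnot(all(c("x", "k", "n") %in% names(data)))
  data <- data[data$n > 0, , drop = FALSE]
  if (nrow(data) < 4)
    stop("need at least 4 levels with n > 0 to fit", call. = FALSE)
  if (any(data$k < 0 | data$k > data$n))
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)

  degenerate <- all(data$k == 0) || all(data$k == data$n)

  lo <- opts$lower; hi <- opts$upper
  obj <- function(par) {
    v <- neg_log_likelihood(list(alpha = par[1], beta = par[2], gamma = par[3],
                                 lam = par[4], eta = par[5]), data)
    if (!is.finite(v)) 1e10 else v
  }

  ## coarse grid over (alpha, beta), nuisances at mild defaults
  alphas <- exp(seq(log(max(lo[1], 0.15)), log(hi[1]), length.out = opts$grid_alpha))
  betas <- exp(seq(log(max(lo[2], 0.5)), log(12), length.out = opts$grid_beta))
  grid <- expand.grid(alpha = alphas, beta = betas)
  grid_nll <- vapply(seq_len(nrow(grid)),
                     function(i) obj(c(grid$alpha[i], grid$beta[i], 0.02, 0.02, 0)),
                     numeric(1))
  starts <- grid[order(grid_nll)[seq_len(opts$n_starts)], , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(starts$alpha[i], starts$beta[i], 0.02, 0.02, 0.01)
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = opts$maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("optimization failed from every start", call. = FALSE)

  ## derivative-free polish: L-BFGS-B's finite-difference line search can
  ## abort near the eta = 0 boundary even at the optimum, so refine with a
  ## bound-projected Nelder-Mead and take its convergence signal
  proj <- function(par) pmin(pmax(par, lo), hi)
  pol <- stats::optim(best$par, function(par) obj(proj(par)),
                      method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  if (pol$value <= best$value) {
    best$par <- proj(pol$par)
    best$value <- pol$value
    best$convergence <- min(best$convergence, pol$convergence)
  }

  fit <- structure(
    list(alpha = best$par[1], beta = best$par[2], gamma = best$par[3],
         lam = best$par[4], eta = best$par[5], nll = best$value,
         converged = best$convergence == 0 && !degenerate,
         degenerate = degenerate, n_levels = nrow(data)),
    class = "psychometric_fit")
  fit$threshold_defined <- (1 - fit$lam) > 0.5
  fit$threshold <- if (fit$threshold_defined)
    suppressWarnings(threshold_50(fit)) else NA_real_
  fit$slope <- if (fit$threshold_defined)
    suppressWarnings(slope_at_threshold(fit)) else NA_real_
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(paste0("<psychometric_fit: threshold %.3f channels, slope %.3f,",
                     " gamma %.3f, lam %.3f, eta %.3f, nll %.2f%s>\n"),
              x$threshold, x$slope, x$gamma, x$lam, x$eta, x$nll,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' 50% intelligibility threshold in channels
#'
#' Solves `gamma + (1 - gamma - lam) F(x*) = 0.5` for the absolute 50%
#' correct point (not the midpoint of the asymptote range) and returns
#' `2^x*`, the number of channels. The scaled Weibull has an exact inverse,
#' `x* = alpha * (-log(1 - q))^(1/beta)` with
#' `q = (0.5 - gamma) / (1 - gamma - lam)`, so the solution is closed-form.
#'
#' @param fit A `psychometric_fit` or any list with `alpha`, `beta`,
#'   `gamma`, `lam`.
#' @return Threshold in channels (>= 1). If the upper asymptote `1 - lam`
#'   never reaches 0.5 the threshold is undefined: a warning of class
#'   `undefined_threshold` is signalled and `NA` returned. A floor `gamma`
#'   at or above 0.5 pins the threshold to 1 channel.
#' @export
threshold_50 <- function(fit) {
  if (1 - fit$lam <= 0.5) {
    warning(warningCondition(
      "upper asymptote (1 - lam) does not reach 50%: threshold undefined",
      class = "undefined_threshold"))
    return(NA_real_)
  }
  q <- (0.5 - fit$gamma) / (1 - fit$gamma - fit$lam)
  if (q <= 0) return(1) # floor already above 50%: threshold at the 1-channel floor
  x_star <- fit$alpha * (-log(1 - q))^(1 / fit$beta)
  2^x_star
}

#' Slope of the psychometric function at the 50% threshold
#'
#' Analytic derivative of `p(x)` on the log2-channel axis evaluated at the
#' 50% point: `(1 - gamma - lam) * (beta/alpha) (x*/alpha)^(beta-1)
#' exp(-(x*/alpha)^beta)`.
#'
#' @inheritParams threshold_50
#' @return Slope in proportion correct per log2 channel; `NA` (with the
#'   same `undefined_threshold` warning) when the threshold is undefined.
#' @export
slope_at_threshold <- function(fit) {
  thr <- suppressWarnings(threshold_50(fit))
  if (is.na(thr)) {
    warning(warningCondition(
      "threshold undefined: slope at threshold undefined",
      class = "undefined_threshold"))
    return(NA_real_)
  }
  x_star <- log2(thr)
  u <- (x_star / fit$alpha)^fit$beta
  (1 - fit$gamma - fit$lam) * (fit$beta / fit$alpha) *
    (x_star / fit$alpha)^(fit$beta - 1) * exp(-u)
}

#' Convert a (threshold, slope) summary to Weibull scale and shape
#'
#' Group summaries report the 50% threshold in channels and the slope at
#' that point; simulation needs the underlying Weibull `(alpha, beta)`.
#' With `x* = log2(threshold)`, `q = (0.5 - gamma)/(1 - gamma - lam)` and
#' `u = -log(1 - q)`, matching both quantities gives the closed form
#' `beta = slope * x* / ((1 - gamma - lam) * u * (1 - q))` and
#' `alpha = x* / u^(1/beta)`.
#'
#' @param threshold 50% threshold in channels (> 1).
#' @param slope Slope at threshold, proportion per log2 channel (> 0).
#' @param gamma,lam Guess and lapse rates.
#' @return List with `alpha` and `beta`.
#' @export
weibull_from_threshold_slope <- function(threshold, slope, gamma = 0, lam = 0) {
  if (threshold <= 1) stop("`threshold` must exceed 1 channel", call. = FALSE)
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  if (1 - lam <= 0.5 || gamma >= 0.5)
    stop("asymptotes incompatible with a 50% threshold", call. = FALSE)
  x_star <- log2(threshold)
  q <- (0.5 - gamma) / (1 - gamma - lam)
  u <- -log(1 - q)
  beta <- slope * x_star / ((1 - gamma - lam) * u * (1 - q))
  alpha <- x_star / u^(1 / beta)
  list(alpha = alpha, beta = beta)
}
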