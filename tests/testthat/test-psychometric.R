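test_that("the scaled Weibull hits its closed-form anchor points", {
  p0 <- list(alpha = 1.65, beta = 4, gamma = 0.1, lam = 0.05)
  expect_equal(predict_pcorrect(p0, 0), 0.1)            # floor = gamma
  expect_equal(predict_pcorrect(p0, 40), 0.95, tolerance = 1e-9) # ceiling = 1 - lam
  pw <- list(alpha = 1.65, beta = 4, gamma = 0, lam = 0)
  expect_equal(predict_pcorrect(pw, 1.65), 1 - exp(-1)) # p(alpha) = 1 - e^-1
  xs <- seq(0, 6, by = 0.05)
  expect_true(all(diff(predict_pcorrect(p0, xs)) >= 0)) # monotone
  expect_error(predict_pcorrect(list(alpha = -1, beta = 2, gamma = 0, lam = 0), 1),
               "positive")
  expect_error(predict_pcorrect(p0, -0.1), ">= 0")
})

test_that("binomial likelihood matches direct log-mass summation", {
  dat <- data.frame(x = log2(c(2, 4, 8, 16)), k = c(2, 5, 9, 12),
                    n = rep(12, 4))
  par <- list(alpha = 2, beta = 3, gamma = 0.02, lam = 0.01, eta = 0)
  p <- 0.02 + (1 - 0.03) * (1 - exp(-(dat$x / 2)^3))
  expect_equal(neg_log_likelihood(par, dat), binom_nll_oracle(dat$k, dat$n, p),
               tolerance = 1e-10)
})

test_that("beta-binomial likelihood converges to the binomial as eta -> 0", {
  dat <- data.frame(x = log2(c(2, 3, 6, 12, 24)), k = c(1, 4, 8, 11, 12),
                    n = rep(12, 5))
  base <- list(alpha = 1.8, beta = 2.5, gamma = 0.03, lam = 0.02)
  nll0 <- neg_log_likelihood(c(base, eta = 0), dat)
  nll_eps <- neg_log_likelihood(c(base, eta = 1e-4), dat)
  expect_lt(abs(nll_eps - nll0), 1e-4)
  expect_error(neg_log_likelihood(c(base, eta = 1), dat), "eta")
})

test_that("likelihood is additive over duplicated data", {
  dat <- data.frame(x = log2(c(2, 4, 8, 16)), k = c(3, 6, 10, 12), n = rep(12, 4))
  par <- list(alpha = 2, beta = 3, gamma = 0.02, lam = 0.01, eta = 0.2)
  expect_equal(neg_log_likelihood(par, rbind(dat, dat)),
               2 * neg_log_likelihood(par, dat), tolerance = 1e-10)
})

test_that("fitting noiseless large-n data recovers the threshold within 2%", {
  truth <- listener_params(3.14, 1.08, gamma = 0.04, lam = 0.02)
  x <- log2(1:24)
  n <- rep(1200, 24)
  p <- predict_pcorrect(truth, x)
  dat <- data.frame(x = x, k = round(n * p), n = n)
  fit <- fit_psychometric(dat)
  expect_true(fit$converged)
  expect_lt(abs(fit$threshold - 3.14) / 3.14, 0.02)
  expect_lt(abs(fit$slope - 1.08) / 1.08, 0.10)
})

test_that("the optimizer dominates an exhaustive grid on toy data", {
  dat <- data.frame(x = log2(c(2, 3, 4, 6, 10, 18)),
                    k = c(1, 3, 6, 9, 11, 12), n = rep(12, 6))
  grid <- expand.grid(alpha = seq(0.5, 4, length.out = 12),
                      beta = seq(0.5, 8, length.out = 10),
                      gamma = seq(0, 0.25, length.out = 6),
                      lam = seq(0, 0.25, length.out = 6))
  grid_nll <- vapply(seq_len(nrow(grid)), function(i) {
    neg_log_likelihood(list(alpha = grid$alpha[i], beta = grid$beta[i],
                            gamma = grid$gamma[i], lam = grid$lam[i], eta = 0),
                       dat)
  }, numeric(1))
  fit <- fit_psychometric(dat)
  expect_lte(fit$nll, min(grid_nll))
})

test_that("fitting is deterministic and flags degenerate data", {
  design <- build_stimulus_list(4)
  tt <- simulate_listener(listener_params(3.5, 1.0, gamma = 0.02), design, seed = 8)
  pd <- aggregate_trials(tt)
  f1 <- fit_psychometric(pd)
  f2 <- fit_psychometric(pd)
  expect_identical(f1[c("alpha", "beta", "gamma", "lam", "eta", "nll")],
                   f2[c("alpha", "beta", "gamma", "lam", "eta", "nll")])

  all_zero <- data.frame(x = log2(c(2, 4, 8, 16)), k = rep(0, 4), n = rep(12, 4))
  fz <- fit_psychometric(all_zero)
  expect_true(fz$degenerate)
  expect_false(fz$converged)
  expect_error(fit_psychometric(all_zero[1:3, ]), "4 levels")
})

test_that("threshold_50 solves the absolute 50% point", {
  # gamma = lam = 0: x* = alpha * (ln 2)^(1/beta)
  f <- list(alpha = 1.7, beta = 4, gamma = 0, lam = 0)
  expect_equal(threshold_50(f), 2^(1.7 * log(2)^(1 / 4)), tolerance = 1e-12)
  # large beta sharpens the curve onto its scale: threshold -> 2^alpha
  f2 <- list(alpha = log2(3.14), beta = 60, gamma = 0, lam = 0)
  expect_equal(threshold_50(f2), 3.14, tolerance = 0.02)
  # near-pathological guess rate floors the threshold at ~1 channel
  f3 <- list(alpha = 1.7, beta = 4, gamma = 0.5 - 1e-6, lam = 0)
  expect_lt(threshold_50(f3), 1.05)
  # asymptote below 50%: undefined-threshold signal, not a numeric failure
  f4 <- list(alpha = 1.7, beta = 4, gamma = 0, lam = 0.6)
  expect_warning(thr <- threshold_50(f4), class = "undefined_threshold")
  expect_true(is.na(thr))
})

test_that("slope at threshold matches a central finite difference", {
  fd_slope <- function(f) {
    x_star <- log2(suppressWarnings(threshold_50(f)))
    h <- 1e-5
    (predict_pcorrect(f, x_star + h) - predict_pcorrect(f, x_star - h)) / (2 * h)
  }
  f <- list(alpha = 1.65, beta = 4, gamma = 0, lam = 0)
  expect_equal(slope_at_threshold(f), fd_slope(f), tolerance = 1e-6)
  # compressed range near the lapse limit
  f2 <- list(alpha = 1.65, beta = 4, gamma = 0, lam = 0.49)
  expect_equal(slope_at_threshold(f2), fd_slope(f2), tolerance = 1e-6)
  # steeper shape, steeper slope
  f3 <- list(alpha = 1.65, beta = 8, gamma = 0, lam = 0)
  expect_gt(slope_at_threshold(f3), slope_at_threshold(f))
  # undefined threshold propagates
  f4 <- list(alpha = 1.65, beta = 4, gamma = 0, lam = 0.6)
  expect_warning(s <- slope_at_threshold(f4), class = "undefined_threshold")
  expect_true(is.na(s))
})

test_that("threshold/slope reparameterization round-trips through the Weibull", {
  for (thr in c(2.5, 3.14, 5.5)) {
    for (sl in c(0.6, 1.08)) {
      ab <- weibull_from_threshold_slope(thr, sl, gamma = 0.04, lam = 0.02)
      f <- list(alpha = ab$alpha, beta = ab$beta, gamma = 0.04, lam = 0.02)
      expect_equal(threshold_50(f), thr, tolerance = 1e-9)
      expect_equal(slope_at_threshold(f), sl, tolerance = 1e-9)
    }
  }
})

test_that("recovery stays within 10% (median) on the standard design", {
  design <- build_stimulus_list(21)
  spec <- dementia_cohort_spec()
  conds <- spec[spec$group %in% c("Controls", "lvPPA"), ]
  for (g in seq_len(nrow(conds))) {
    row <- conds[g, ]
    pars <- draw_group_parameters(row, 100, seed = derive_seed(777, g))
    ratio <- vapply(seq_len(100), function(i) {
      lp <- listener_params(pars$threshold[i], pars$slope[i], pars$gamma[i],
                            pars$lam[i], pars$eta[i])
      tt <- simulate_listener(lp, design, seed = derive_seed(778, g, i))
      fit_psychometric(aggregate_trials(tt))$threshold / pars$threshold[i]
    }, numeric(1))
    expect_lt(abs(stats::median(ratio) - 1), 0.10)
  }
})

test_that("true parameters sit within likelihood reach of the MLE", {
  design <- build_stimulus_list(31)
  lp <- listener_params(3.14, 1.08, gamma = 0.04, lam = 0.02)
  tt <- simulate_listener(lp, design, seed = 55)
  pd <- aggregate_trials(tt)
  fit <- fit_psychometric(pd)
  nll_true <- neg_log_likelihood(lp, pd$data)
  expect_gte(nll_true, fit$nll) # MLE is the optimum
  # chi-square consistent distance: 2 * dNLL below the 99.9% chi2_5 quantile
  expect_lt(2 * (nll_true - fit$nll), qchisq(0.999, df = 5))
})
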