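test_that("synthetic utterances are deterministic, bounded and distinct", {
  u1 <- synth_utterance("587", 16000, seed = 3)
  u2 <- synth_utterance("587", 16000, seed = 3)
  expect_identical(u1$samples, u2$samples)
  expect_equal(u1$rate, 16000)
  expect_lte(max(abs(u1$samples)), 0.5 + 1e-12)
  expect_gt(duration(u1), 1.2)

  u3 <- synth_utterance("123", 16000, seed = 3)
  e1 <- extract_envelope(u1, 30)
  e3 <- extract_envelope(u3, 30)
  expect_lt(cor(e1$samples, e3$samples), 0.9) # distinct stimuli

  expect_error(synth_utterance("87"), "three-digit")
  expect_error(synth_utterance("099"), "three-digit")
})

test_that("stimulus list satisfies the 100-item design invariants", {
  sl <- build_stimulus_list(42)
  expect_equal(nrow(sl), 100)
  expect_equal(sum(sl$level == "clear"), 4)
  voc <- sl[sl$level != "clear", ]
  expect_equal(nrow(voc), 96)
  expect_equal(as.vector(table(as.integer(voc$level))), rep(4L, 24))
  expect_equal(anyDuplicated(sl$digits), 0L) # all 100 numbers distinct
  # order: clear first, then channels descending 24 -> 1
  expect_equal(sl$level[1:4], rep("clear", 4))
  expect_true(all(diff(as.integer(voc$level)) <= 0))

  sl2 <- build_stimulus_list(43)
  expect_false(identical(sl$digits, sl2$digits))
  expect_identical(sl$level, sl2$level) # design fixed, content randomized
})

test_that("a steep listener shows floor and ceiling limiting behaviour", {
  design <- build_stimulus_list(5)
  lp <- listener_params(4, 3.5, gamma = 0, lam = 0)
  tt <- simulate_listener(lp, design, seed = 6)
  pd <- aggregate_trials(tt)$data
  expect_lte(sum(pd$k[pd$level <= 2]), 2) # near zero at 1-2 channels
  expect_gte(sum(pd$k[pd$level >= 16]) / sum(pd$n[pd$level >= 16]), 0.95)
})

test_that("per-level counts are binomial at eta = 0 and overdispersed at eta = 0.3", {
  design <- build_stimulus_list(7)
  n_rep <- 150
  sim_k <- function(eta) {
    lp <- listener_params(3.14, 1.08, gamma = 0.02, lam = 0.01, eta = eta)
    t(vapply(seq_len(n_rep), function(i) {
      tt <- simulate_listener(lp, design, seed = derive_seed(500 + i, eta * 10))
      aggregate_trials(tt)$data$k
    }, numeric(24)))
  }
  d0 <- dispersion_stat(sim_k(0), 12)
  p0 <- pchisq(d0$stat, d0$df, lower.tail = FALSE)
  expect_gt(p0, 0.01) # consistent with Binomial(12, p)

  d3 <- dispersion_stat(sim_k(0.3), 12)
  p3 <- pchisq(d3$stat, d3$df, lower.tail = FALSE)
  expect_lt(p3, 0.01) # extra-binomial: dispersion test significant
})

test_that("cohort draws respect degenerate SDs, truncation and group sizes", {
  spec <- dementia_cohort_spec()
  expect_equal(sum(spec$n), 74)

  # SD = 0 everywhere: all listeners identical
  degen <- spec[1, ]
  degen[, grep("_sd$", names(degen))] <- 0
  pars <- draw_group_parameters(degen, 10, seed = 1)
  expect_equal(nrow(unique(pars)), 1)

  # law of large numbers: sample mean within 3 SE of spec mean
  ctrl <- spec[spec$group == "Controls", ]
  thr <- draw_group_parameters(ctrl, 400, seed = 2)$threshold
  se <- ctrl$threshold_sd / sqrt(400)
  expect_lt(abs(mean(thr) - ctrl$threshold_mean), 3 * se)

  # truncation never produces invalid parameters (wide-SD worst case)
  lv <- spec[spec$group == "lvPPA", ]
  p <- draw_group_parameters(lv, 500, seed = 3)
  expect_true(all(p$threshold > 1))
  expect_true(all(p$slope > 0))
  expect_true(all(p$gamma >= 0 & p$gamma <= 0.25))
  expect_true(all(p$lam >= 0 & p$lam <= 0.25))
  expect_true(all(p$eta >= 0 & p$eta < 1))
})

test_that("simulate_cohort returns matching trials and truth tables", {
  spec <- dementia_cohort_spec()[c(1, 5), ]
  spec$n <- c(3L, 2L)
  design <- build_stimulus_list(2)
  sim <- simulate_cohort(spec, design, seed = 10)
  expect_equal(nrow(sim$truth), 5)
  expect_equal(nrow(sim$trials), 5 * 100)
  expect_setequal(unique(sim$trials$participant_id), sim$truth$participant_id)
  expect_equal(as.vector(table(sim$truth$group)[spec$group]), spec$n)

  sim2 <- simulate_cohort(spec, design, seed = 10)
  expect_identical(sim$trials, sim2$trials) # reproducible from the seed

  bad <- spec; bad$n[1] <- 0L
  expect_error(simulate_cohort(bad, design, seed = 1), "non-empty")
})

test_that("fitting recovers the generating threshold at high trial counts", {
  # 10x the standard trials-per-level; bias across replicates under 5%
  design <- make_flat_design(40)
  true_thr <- 3.14
  lp <- listener_params(true_thr, 1.08, gamma = 0.04, lam = 0.0)
  fitted <- vapply(seq_len(100), function(i) {
    tt <- simulate_listener(lp, design, seed = derive_seed(900, i))
    fit_psychometric(aggregate_trials(tt))$threshold
  }, numeric(1))
  expect_lt(abs(mean(fitted) - true_thr) / true_thr, 0.05)
})
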