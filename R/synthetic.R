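#' Synthesize a stand-in spoken three-digit number
#'
#' Generates a harmonic-complex "utterance" (~1.5 s) standing in for a
#' recorded spoken three-digit number. Each digit becomes one voiced
#' segment whose fundamental, spectral tilt (hence centroid trajectory),
#' attack time and amplitude-modulation rate depend on the digit value, so
#' different numbers have distinct broadband envelopes and spectra. All
#' energy lies within \[100, 6400\] Hz. Deterministic per (digits, seed).
#'
#' @param digits A three-digit string or integer in 100..999.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed for the small per-token jitter.
#' @param peak Peak amplitude of the output. The default 0.5 leaves
#'   headroom so downstream noise carriers (whose crest factor exceeds a
#'   harmonic complex's) stay below full scale after RMS matching.
#' @return An [audio_signal()], peak-normalized to `peak`.
#' @export
synth_utterance <- function(digits, rate = 16000, seed = 1L, peak = 0.5) {
  digits <- as.character(digits)
  if (!grepl("^[0-9]{3}$", digits) || as.integer(digits) < 100)
    stop("`digits` must be a three-digit number in 100..999", call. = FALSE)
  dvec <- as.integer(strsplit(digits, "")[[1]])
  seg_dur <- 0.42
  gap_dur <- 0.06
  withr::with_seed(seed, {
    segs <- lapply(seq_along(dvec), function(i) {
      d <- dvec[i]
      n <- round(seg_dur * rate)
      t <- seq_len(n) / rate
      f0 <- 110 * 2^(d / 14) * (1 + stats::runif(1, -0.01, 0.01))
      tilt <- 0.7 + 0.08 * d # spectral rolloff exponent -> centroid varies by digit
      nh <- floor(6400 / f0)
      x <- numeric(n)
      for (h in seq_len(nh)) {
        fh <- h * f0
        if (fh < 100) next
        x <- x + h^(-tilt) * sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
      }
      ## digit-dependent amplitude contour: attack + syllabic AM
      attack <- 0.03 + 0.015 * d
      am_rate <- 2.5 + 0.4 * d
      env <- pmin(t / attack, 1) * pmin((seg_dur - t) / 0.05, 1)
      env <- pmax(env, 0) * (1 - 0.35 * (0.5 - 0.5 * cos(2 * pi * am_rate * t)))
      c(x * env, numeric(round(gap_dur * rate)))
    })
  })
  x <- unlist(segs)
  audio_signal(peak * x / max(abs(x)), rate)
}

#' Build the 100-item stimulus design
#'
#' The behavioural design: 100 distinct spoken three-digit numbers, 4
#' presented as clear (unprocessed) speech followed by 4 at each vocoding
#' channel count from 24 down to 1, in order of progressively decreasing
#' intelligibility. The level structure is fixed; which number lands on
#' which trial is randomized by `seed`.
#'
#' @param seed Integer seed for sampling the numbers.
#' @return A data frame of class `stimulus_list` with columns
#'   `stimulus_id`, `digits` (three-digit string), `level` (`"clear"` or
#'   the channel count as a string) and `audio_file` (manifest reference).
#' @export
build_stimulus_list <- function(seed = 1L) {
  numbers <- withr::with_seed(seed, sample(100:999, 100))
  level <- c(rep("clear", 4), rep(as.character(24:1), each = 4))
  out <- data.frame(
    stimulus_id = seq_len(100),
    digits = sprintf("%03d", numbers),
    level = level,
    audio_file = sprintf("stim%03d_lev%s.wav", seq_len(100),
                         gsub("clear", "clr", level)),
    stringsAsFactors = FALSE)
  class(out) <- c("stimulus_list", "data.frame")
  out
}

#' Listener parameters
#'
#' Ground-truth psychometric parameters for one simulated listener, stated
#' in the reporting scale — 50% threshold in channels and slope at
#' threshold — and converted internally to the Weibull scale/shape via
#' [weibull_from_threshold_slope()].
#'
#' @param threshold True 50% threshold in channels (> 1).
#' @param slope Slope at threshold, proportion correct per log2 channel.
#' @param gamma Guess rate in \[0, 0.25\].
#' @param lam Lapse rate in \[0, 0.25\].
#' @param eta Overdispersion in \[0, 1).
#' @return An object of class `listener_params` with fields `threshold`,
#'   `slope`, `gamma`, `lam`, `eta`, `alpha`, `beta`.
#' @export
listener_params <- function(threshold, slope, gamma = 0, lam = 0, eta = 0) {
  if (gamma < 0 || gamma > 0.25 || lam < 0 || lam > 0.25)
    stop("`gamma` and `lam` must lie in [0, 0.25]", call. = FALSE)
  if (gamma + lam >= 1) stop("gamma + lam must be < 1", call. = FALSE)
  if (eta < 0 || eta >= 1) stop("`eta` must lie in [0, 1)", call. = FALSE)
  ab <- weibull_from_threshold_slope(threshold, slope, gamma, lam)
  structure(list(threshold = threshold, slope = slope, gamma = gamma,
                 lam = lam, eta = eta, alpha = ab$alpha, beta = ab$beta),
            class = "listener_params")
}

#' Simulate one listener's trial responses
#'
#' For each trial at `x = log2(channels)` the digit-correct probability is
#' `p = predict_pcorrect(params, x)`; clear-speech trials use
#' `p = 1 - lam`. Under overdispersion (`eta > 0`) a trial-level latent
#' probability is drawn from a Beta distribution with mean `p` and
#' variance `eta^2 p (1 - p)` and shared by the trial's three digit slots
#' (digits within a trial share one acoustic token, which is what makes
#' per-level counts extra-binomial); with `eta = 0` the digits are plain
#' Bernoulli(p).
#'
#' @param params A [listener_params()].
#' @param design A [build_stimulus_list()] data frame.
#' @param seed Integer seed.
#' @param participant_id,group Labels copied into the output.
#' @return A `trial_table` data frame: `participant_id`, `group`,
#'   `trial_index`, `level`, `target_digits`, `response_digits`,
#'   `digits_correct`.
#' @export
simulate_listener <- function(params, design, seed = 1L,
                              participant_id = "P1", group = "sim") {
  stopifnot(inherits(params, "listener_params"))
  if (params$eta >= 1) stop("`eta` must be < 1", call. = FALSE)
  n_tr <- nrow(design)
  withr::with_seed(seed, {
    resp <- character(n_tr)
    ncorr <- integer(n_tr)
    for (i in seq_len(n_tr)) {
      lev <- design$level[i]
      p <- if (lev == "clear") 1 - params$lam
           else predict_pcorrect(params, log2(as.numeric(lev)))
      if (params$eta > 0) {
        pc <- min(max(p, 1e-6), 1 - 1e-6)
        nu <- 1 / params$eta^2 - 1
        p <- stats::rbeta(1, pc * nu, (1 - pc) * nu)
      }
      tgt <- as.integer(strsplit(design$digits[i], "")[[1]])
      ok <- stats::rbinom(3, 1, p) == 1
      rd <- tgt
      for (j in which(!ok)) rd[j] <- sample(setdiff(0:9, tgt[j]), 1)
      resp[i] <- paste(rd, collapse = "")
      ncorr[i] <- sum(ok)
    }
  })
  out <- data.frame(
    participant_id = participant_id, group = group,
    trial_index = seq_len(n_tr), level = design$level,
    target_digits = design$digits, response_digits = resp,
    digits_correct = ncorr, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Five-group cohort specification for a dementia study
#'
#' Default cohort: healthy older controls and four dementia syndromes
#' (typical Alzheimer's disease and the logopenic, non-fluent/agrammatic
#' and semantic variants of primary progressive aphasia), with group sizes
#' and per-group psychometric parameter means/SDs matching published
#' behavioural profiles for noise-vocoded digit perception in these
#' populations: controls sit near a 3-channel threshold with little
#' spread, patient groups show elevated, more variable thresholds.
#'
#' @return A `cohort_spec` data frame with columns `group`, `n`, and
#'   `<param>_mean` / `<param>_sd` for threshold, slope, lam, gamma, eta.
#' @export
dementia_cohort_spec <- function() {
  out <- data.frame(
    group = c("Controls", "AD", "lvPPA", "nfvPPA", "svPPA"),
    n = c(25L, 19L, 8L, 10L, 12L),
    threshold_mean = c(3.14, 4.33, 5.35, 4.68, 3.55),
    threshold_sd   = c(0.27, 1.25, 2.13, 2.22, 0.53),
    slope_mean     = c(1.08, 0.79, 0.82, 0.81, 0.95),
    slope_sd       = c(0.90, 0.27, 0.36, 0.27, 0.46),
    lam_mean       = c(0.00, 0.02, 0.03, 0.02, 0.02),
    lam_sd         = c(0.01, 0.02, 0.03, 0.02, 0.03),
    gamma_mean     = c(0.04, 0.00, 0.00, 0.00, 0.00),
    gamma_sd       = c(0.07, 0.01, 0.01, 0.00, 0.00),
    eta_mean       = c(0.00, 0.04, 0.04, 0.00, 0.00),
    eta_sd         = c(0.00, 0.10, 0.10, 0.00, 0.00),
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_spec", "data.frame")
  out
}

## truncated-normal draw by inverse-CDF; sd = 0 degenerates to the
## (clamped) mean
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw listener parameters for one group
#'
#' Samples per-listener psychometric parameters from normal distributions
#' truncated to their valid ranges: threshold > 1 channel (lower bound
#' 1.05 so the log2 transform stays away from 0), slope >= 0.05,
#' guess/lapse rates in \[0, 0.25\], overdispersion in \[0, 0.95\].
#'
#' @param spec_row One row of a [dementia_cohort_spec()]-style data frame.
#' @param n Number of listeners.
#' @param seed Integer seed.
#' @return A data frame with columns `threshold`, `slope`, `gamma`, `lam`,
#'   `eta`, one row per listener.
#' @export
draw_group_parameters <- function(spec_row, n, seed = 1L) {
  if (n < 1) stop("group must contain at least one listener", call. = FALSE)
  withr::with_seed(seed, {
    data.frame(
      threshold = rtrunc_norm(n, spec_row$threshold_mean, spec_row$threshold_sd,
                              lo = 1.05),
      slope = rtrunc_norm(n, spec_row$slope_mean, spec_row$slope_sd, lo = 0.05),
      gamma = rtrunc_norm(n, spec_row$gamma_mean, spec_row$gamma_sd,
                          lo = 0, hi = 0.25),
      lam = rtrunc_norm(n, spec_row$lam_mean, spec_row$lam_sd,
                        lo = 0, hi = 0.25),
      eta = rtrunc_norm(n, spec_row$eta_mean, spec_row$eta_sd,
                        lo = 0, hi = 0.95))
  })
}

#' Simulate a multi-group cohort
#'
#' Draws each listener's ground-truth parameters from the group's
#' truncated-normal distributions ([draw_group_parameters()]) and
#' simulates their full trial table on the given stimulus design. Seeds
#' for the per-group draws and per-listener responses are derived
#' hierarchically from `seed`.
#'
#' @param spec A `cohort_spec` data frame (e.g. [dementia_cohort_spec()]).
#' @param design A [build_stimulus_list()] design.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim`: `trials` (all listeners'
#'   `trial_table` rows) and `truth` (one row per listener:
#'   `participant_id`, `group`, `threshold`, `slope`, `gamma`, `lam`,
#'   `eta`).
#' @export
simulate_cohort <- function(spec, design, seed = 1L) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1)
  if (any(spec$n < 1)) stop("all groups must be non-empty", call. = FALSE)
  if (anyDuplicated(spec$group)) stop("group labels must be unique", call. = FALSE)
  trials <- list(); truth <- list()
  pid <- 0L
  for (g in seq_len(nrow(spec))) {
    row <- spec[g, ]
    pars <- draw_group_parameters(row, row$n, derive_seed(seed, "draw", g))
    for (i in seq_len(row$n)) {
      pid <- pid + 1L
      id <- sprintf("%s_%02d", row$group, i)
      lp <- listener_params(pars$threshold[i], pars$slope[i], pars$gamma[i],
                            pars$lam[i], pars$eta[i])
      trials[[pid]] <- simulate_listener(lp, design,
                                         seed = derive_seed(seed, "listener", pid),
                                         participant_id = id, group = row$group)
      truth[[pid]] <- data.frame(participant_id = id, group = row$group,
                                 threshold = pars$threshold[i],
                                 slope = pars$slope[i], gamma = pars$gamma[i],
                                 lam = pars$lam[i], eta = pars$eta[i],
                                 stringsAsFactors = FALSE)
    }
  }
  structure(list(trials = do.call(rbind, trials),
                 truth = do.call(rbind, truth)),
            class = "cohort_sim")
}
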