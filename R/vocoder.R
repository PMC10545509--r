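#' Vocoder configuration
#'
#' Settings for the channel vocoder. Channels partition \[`f_lo`, `f_hi`\]
#' into `n_channels` contiguous bands, equally spaced on a log-frequency
#' axis (the standard noise-vocoder choice, since cochlear frequency
#' resolution is approximately logarithmic).
#'
#' @param n_channels Number of spectral channels (>= 1).
#' @param f_lo,f_hi Lower/upper band limits in Hz; `0 < f_lo < f_hi`, and
#'   `f_hi` must stay below the Nyquist frequency of any signal processed.
#' @param filter_order Band-pass filter order (even, >= 2). Filters are
#'   Butterworth, applied forward-backward (zero phase), so the effective
#'   magnitude response is the squared design response.
#' @param env_cutoff Envelope low-pass cutoff in Hz. 30 Hz keeps syllabic
#'   and phonemic amplitude modulation while discarding periodicity.
#' @param env_method Envelope extractor: half-wave rectification (default)
#'   or Hilbert magnitude, both followed by the same low-pass.
#' @param seed Integer seed for the noise carriers; `vocode()` is a pure
#'   function of (signal, config).
#' @return An object of class `vocoder_config`.
#' @export
vocoder_config <- function(n_channels, f_lo = 100, f_hi = 6400,
                           filter_order = 4, env_cutoff = 30,
                           env_method = c("rectify", "hilbert"),
                           seed = 1L) {
  env_method <- match.arg(env_method)
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 1 ||
      n_channels != round(n_channels))
    stop("`n_channels` must be a single integer >= 1", call. = FALSE)
  if (!(f_lo > 0 && f_hi > f_lo))
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (filter_order < 2 || filter_order %% 2 != 0)
    stop("`filter_order` must be an even integer >= 2", call. = FALSE)
  if (env_cutoff <= 0) stop("`env_cutoff` must be positive", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), f_lo = f_lo, f_hi = f_hi,
                 filter_order = as.integer(filter_order),
                 env_cutoff = env_cutoff, env_method = env_method,
                 seed = as.integer(seed)),
            class = "vocoder_config")
}

#' Build the vocoder filterbank
#'
#' Partitions \[`f_lo`, `f_hi`\] into `n_channels` contiguous band-pass
#' filters with edges equally spaced in log frequency:
#' `edge_k = f_lo * (f_hi/f_lo)^(k / n_channels)`.
#'
#' @param config A [vocoder_config()].
#' @param rate Sampling rate (Hz) of the signals the bank will filter.
#' @return An object of class `filterbank`: `edges` (length
#'   `n_channels + 1`) and a list of `signal::butter` filter definitions.
#' @export
make_filterbank <- function(config, rate) {
  stopifnot(inherits(config, "vocoder_config"))
  if (config$f_hi >= rate / 2)
    stop("f_hi must be below the Nyquist frequency (rate/2 = ", rate / 2, " Hz)",
         call. = FALSE)
  n <- config$n_channels
  edges <- config$f_lo * (config$f_hi / config$f_lo)^(seq(0, n) / n)
  filters <- lapply(seq_len(n), function(k) {
    signal::butter(config$filter_order / 2L,
                   c(edges[k], edges[k + 1L]) / (rate / 2),
                   type = "pass")
  })
  structure(list(edges = edges, filters = filters, rate = rate,
                 order = config$filter_order),
            class = "filterbank")
}

#' @export
print.filterbank <- function(x, ...) {
  cat(sprintf("<filterbank: %d channels, %.0f-%.0f Hz, order-%d Butterworth @ %g Hz>\n",
              length(x$filters), x$edges[1], x$edges[length(x$edges)],
              x$order, x$rate))
  invisible(x)
}

## zero-phase band filter; filtfilt squares the magnitude response
band_filter <- function(flt, samples) signal::filtfilt(flt, samples)

#' Extract the amplitude envelope of a band signal
#'
#' Half-wave rectification (or Hilbert magnitude) followed by a 4th-order
#' zero-phase Butterworth low-pass at `env_cutoff`. The result is clamped
#' to be non-negative (the low-pass can undershoot slightly).
#'
#' @param band An [audio_signal()], typically already band-pass filtered.
#' @param env_cutoff Low-pass cutoff in Hz; must be below Nyquist.
#' @param method `"rectify"` or `"hilbert"`.
#' @return An [audio_signal()] with the same length and rate: the envelope.
#' @export
extract_envelope <- function(band, env_cutoff = 30,
                             method = c("rectify", "hilbert")) {
  stopifnot(inherits(band, "audio_signal"))
  method <- match.arg(method)
  if (env_cutoff >= band$rate / 2)
    stop("env_cutoff must be below the Nyquist frequency", call. = FALSE)
  x <- band$samples
  demod <- if (method == "rectify") pmax(x, 0) else Mod(analytic_signal(x))
  lp <- signal::butter(4, env_cutoff / (band$rate / 2), type = "low")
  env <- pmax(signal::filtfilt(lp, demod), 0)
  audio_signal(env, band$rate)
}

## analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Noise-vocode a signal
#'
#' Divides the input into `n_channels` contiguous log-spaced frequency
#' bands, extracts each band's low-pass amplitude envelope, multiplies it
#' onto a fresh white Gaussian noise carrier, re-filters the product into
#' the band (bounding spectral splatter), and sums the channels. The output
#' is RMS-matched to the input. This removes spectral fine structure while
#' preserving the slower temporal modulation in each band; with few
#' channels the result keeps the rhythm of speech but little of its
#' spectral identity.
#'
#' @param signal An [audio_signal()].
#' @param config A [vocoder_config()] valid for `signal$rate`.
#' @return An [audio_signal()] of the same length and rate. Deterministic
#'   given (`signal`, `config`). If RMS matching would push the peak above
#'   1 the whole output is rescaled to peak 1 (never clipped) and the
#'   attribute `"renormalized"` is set to `TRUE`.
#' @export
vocode <- function(signal, config) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "vocoder_config"))
  fb <- make_filterbank(config, signal$rate)
  x <- signal$samples
  n <- length(x)
  out <- numeric(n)
  withr::with_seed(config$seed, {
    for (k in seq_along(fb$filters)) {
      band <- band_filter(fb$filters[[k]], x)
      env <- extract_envelope(audio_signal(band, signal$rate),
                              config$env_cutoff, config$env_method)
      carrier <- stats::rnorm(n)
      out <- out + band_filter(fb$filters[[k]], carrier * env$samples)
    }
  })
  out_rms <- sqrt(mean(out^2))
  if (out_rms == 0)
    stop("vocoded output is silent; input has no energy in the analysis bands",
         call. = FALSE)
  out <- out * (rms(signal) / out_rms)
  renorm <- FALSE
  peak <- max(abs(out))
  if (peak > 1) {
    out <- out / peak
    renorm <- TRUE
  }
  res <- audio_signal(out, signal$rate)
  attr(res, "renormalized") <- renorm
  res
}

#' Log power in fractional-octave bands
#'
#' Summarizes a spectrum as log10 power aggregated into fractional-octave
#' bands between `f_lo` and `f_hi`. Used to compare the spectral shape of
#' an input with its vocoded counterpart.
#'
#' @param x An [audio_signal()].
#' @param f_lo,f_hi Band limits in Hz.
#' @param bands_per_octave Resolution; 3 gives 1/3-octave bands.
#' @return A data frame with `f_center` (Hz) and `level` (log10 power).
#' @export
octave_band_levels <- function(x, f_lo = 100, f_hi = 6400,
                               bands_per_octave = 3) {
  stopifnot(inherits(x, "audio_signal"))
  n <- length(x$samples)
  spec <- Mod(stats::fft(x$samples))^2
  freqs <- (seq_len(n) - 1) * x$rate / n
  half <- freqs <= x$rate / 2
  spec <- spec[half]; freqs <- freqs[half]
  n_bands <- ceiling(log2(f_hi / f_lo) * bands_per_octave)
  edges <- f_lo * 2^(seq(0, n_bands) / bands_per_octave)
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  level <- vapply(seq_len(n_bands), function(b) {
    sel <- freqs >= edges[b] & freqs < edges[b + 1]
    log10(sum(spec[sel]) + 1e-12)
  }, numeric(1))
  data.frame(f_center = centers, level = level)
}

#' Spectral similarity between two signals
#'
#' Pearson correlation of fractional-octave log-spectra; a scalar summary
#' of how much spectral shape survives a transformation.
#'
#' @param a,b Two [audio_signal()] objects at the same rate.
#' @inheritParams octave_band_levels
#' @return Correlation in \[-1, 1\].
#' @export
spectral_similarity <- function(a, b, f_lo = 100, f_hi = 6400,
                                bands_per_octave = 3) {
  la <- octave_band_levels(a, f_lo, f_hi, bands_per_octave)$level
  lb <- octave_band_levels(b, f_lo, f_hi, bands_per_octave)$level
  stats::cor(la, lb)
}
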