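#' Construct an audio signal
#'
#' Lightweight container for a mono sampled waveform. Amplitudes are
#' dimensionless and expected to live in \[-1, 1\]; all downstream synthesis
#' keeps the peak at or below 1.
#'
#' @param samples Numeric vector of sample amplitudes; must be finite.
#' @param rate Sampling rate in Hz; must be a single positive number.
#' @return An object of class `audio_signal` with fields `samples` and `rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(s)
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), peak %.3f, rms %.4f>\n",
              length(x$samples), x$rate, duration(x),
              max(abs(x$samples)), rms(x)))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) length(x$samples) / x$rate

#' Root-mean-square amplitude
#' @param x An `audio_signal` or numeric vector.
#' @return RMS amplitude (dimensionless).
#' @export
rms <- function(x) {
  v <- if (inherits(x, "audio_signal")) x$samples else x
  sqrt(mean(v^2))
}

## ---- WAV I/O -------------------------------------------------------------
## Minimal RIFF/WAVE reader and writer, mono only, 16-bit PCM or 32-bit
## IEEE float. Chunk-walks the file so extra chunks (LIST, fact) are skipped.

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, mono. Amplitudes are returned
#' scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # overall size
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; samples <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate     = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk", call. = FALSE)
      if (fmt$channels != 1L)
        stop("only mono WAV is supported (file has ", fmt$channels, " channels)",
             call. = FALSE)
      if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", sz %/% 2L, size = 2L, signed = TRUE,
                           endian = "little") / 32767
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", sz %/% 4L, size = 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bit)", call. = FALSE)
      }
      if (sz %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L) # skip unknown chunk
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param x An [audio_signal()]; peak amplitude must not exceed 1.
#' @param path Output path.
#' @param encoding `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, encoding = c("pcm16", "float32")) {
  stopifnot(inherits(x, "audio_signal"))
  encoding <- match.arg(encoding)
  if (max(abs(x$samples)) > 1 + 1e-9)
    stop("peak amplitude exceeds 1; rescale before writing", call. = FALSE)
  n <- length(x$samples)
  rate <- as.integer(round(x$rate))
  if (encoding == "pcm16") {
    fmt_code <- 1L; bits <- 16L; bytes <- 2L
  } else {
    fmt_code <- 3L; bits <- 32L; bytes <- 4L
  }
  data_sz <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(rate, con, size = 4L, endian = "little")
  writeBin(as.integer(rate * bytes), con, size = 4L, endian = "little")
  writeBin(bytes, con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4L, endian = "little")
  if (encoding == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(x$samples * 32767))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x$samples, con, size = 4L, endian = "little")
  }
  invisible(path)
}
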