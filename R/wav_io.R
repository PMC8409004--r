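#' Construct a waveform object
#'
#' A `waveform` holds mono audio samples on the amplitude scale \[-1, 1\]
#' together with its sampling rate. All downstream feature extraction assumes
#' the pipeline's working rate of 8000 Hz; use [read_wav()] with
#' `target_rate = 8000` to ingest arbitrary PCM WAV files.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `waveform`: a list with `samples` and `rate`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("sampling rate must be a single positive number")
  }
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz, %.2f s>\n",
              length(x$samples), x$rate, duration_s(x)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a [waveform()].
#' @return Duration in seconds.
#' @export
duration_s <- function(w) length(w$samples) / w$rate

#' Read a PCM WAV file as a mono waveform at a target rate
#'
#' Parses the RIFF/WAVE container directly (16-bit and 8-bit integer PCM and
#' 32-bit IEEE float supported). Multi-channel audio is mixed to mono by the
#' arithmetic mean of channels (exam recordings carry both speakers on one
#' track, so no channel is privileged) before resampling. Rate conversion uses
#' a polyphase anti-aliased resampler ([signal::resample()]) with the rational
#' factor `target_rate / file_rate`.
#'
#' @param path path to a PCM WAV file.
#' @param target_rate desired sampling rate in Hz; the exam pipeline uses 8000.
#' @return A [waveform()] at `target_rate`.
#' @export
read_wav <- function(path, target_rate = 8000) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels  = readBin(fmt_raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate      = readBin(fmt_raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk word padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing fmt/data chunk): ", path)

  # scale by 32767 so write_wav() %>% read_wav() is sample-identical
  x <- switch(as.character(fmt$bits),
    "16" = pmax(-1, readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                            endian = "little", signed = TRUE) / 32767),
    "8"  = pmax(-1, (readBin(data_raw, "integer", length(data_raw), size = 1,
                             signed = FALSE) - 128) / 127),
    "32" = {
      if (fmt$format == 3L) {
        readBin(data_raw, "numeric", length(data_raw) / 4L, size = 4, endian = "little")
      } else stop("unsupported 32-bit integer PCM in ", path)
    },
    stop("unsupported WAV bit depth ", fmt$bits, " in ", path)
  )
  if (length(x) == 0L) stop("zero-length audio in ", path)

  if (fmt$channels > 1L) {
    n_frames <- length(x) %/% fmt$channels
    x <- x[seq_len(n_frames * fmt$channels)]
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  w <- waveform(x, fmt$rate)
  resample_waveform(w, target_rate)
}

#' Resample a waveform to a target rate
#'
#' Identity when the rates already match (bit-identical samples). Otherwise a
#' polyphase anti-aliased rational-factor resampler is applied.
#'
#' @param w a [waveform()].
#' @param target_rate target sampling rate in Hz.
#' @return A [waveform()] at `target_rate`.
#' @export
resample_waveform <- function(w, target_rate) {
  if (w$rate == target_rate) return(w)
  g <- rational_factor(target_rate, w$rate)
  y <- signal::resample(w$samples, p = g[1], q = g[2])
  y <- pmin(1, pmax(-1, as.numeric(y)))
  waveform(y, target_rate)
}

# Reduce p/q to lowest terms (both rates assumed integral Hz).
rational_factor <- function(p, q) {
  p <- as.integer(round(p)); q <- as.integer(round(q))
  g <- function(a, b) if (b == 0L) a else g(b, a %% b)
  d <- g(p, q)
  c(p %/% d, q %/% d)
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param w a [waveform()]; samples are clipped to \[-1, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
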