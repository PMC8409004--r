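#' MFCC feature-extraction configuration
#'
#' The acoustic front end converts 8 kHz mono audio into a sequence of
#' 13-dimensional feature vectors: frames of 25 ms (200 samples) every 10 ms
#' (80 samples), a 256-point periodogram per frame, a 26-filter triangular
#' Mel filterbank spanning 0--4000 Hz, a log, and an orthonormal DCT-II.
#' Cepstral coefficients 2--13 (1-based) are kept; coefficient 1 is discarded
#' and replaced by the log total energy of the raw frame, giving the final
#' vector `[log energy, c2, ..., c13]`.
#'
#' @param rate sampling rate in Hz. Default 8000.
#' @param window_ms analysis window length in milliseconds. Default 25.
#' @param hop_ms hop (stride) between frame starts in milliseconds. Default 10.
#' @param n_dft DFT length; frames are zero-padded up to it. Default 256.
#' @param n_filters number of triangular Mel filters. Default 26.
#' @param keep 1-based cepstral indices retained after the DCT. Default `2:13`.
#' @param window analysis taper: `"rectangular"` (default, the most literal
#'   periodogram) or `"hamming"`.
#' @param eps floor applied to energies before taking logs, so silent audio is
#'   well-defined. Default `1e-10`.
#' @return A `feature_config` list with derived fields `window_len` (samples),
#'   `hop_len` (samples) and `n_bins` (one-sided spectrum length).
#' @export
feature_config <- function(rate = 8000, window_ms = 25, hop_ms = 10,
                           n_dft = 256, n_filters = 26, keep = 2:13,
                           window = c("rectangular", "hamming"),
                           eps = 1e-10) {
  window <- match.arg(window)
  window_len <- as.integer(round(rate * window_ms / 1000))
  hop_len <- as.integer(round(rate * hop_ms / 1000))
  if (n_dft < window_len) stop("n_dft must be >= the window length in samples")
  structure(list(
    rate = rate, window_ms = window_ms, hop_ms = hop_ms,
    window_len = window_len, hop_len = hop_len,
    n_dft = as.integer(n_dft), n_bins = as.integer(n_dft / 2 + 1),
    n_filters = as.integer(n_filters), keep = as.integer(keep),
    window = window, eps = eps
  ), class = "feature_config")
}

#' Number of analysis frames for a signal length
#' @param n signal length in samples.
#' @param cfg a [feature_config()].
#' @return Integer frame count `1 + floor((n - window_len)/hop_len)`.
#' @export
frame_count <- function(n, cfg = feature_config()) {
  if (n < cfg$window_len) stop("signal shorter than one analysis window")
  1L + (as.integer(n) - cfg$window_len) %/% cfg$hop_len
}

#' Slice a waveform into analysis frames
#'
#' Frame `t` (1-based) covers samples `[(t-1)*hop + 1, (t-1)*hop + window_len]`;
#' trailing samples that do not fill a complete window are dropped.
#'
#' @param w a [waveform()] at the configured rate.
#' @param cfg a [feature_config()].
#' @return A `T x window_len` matrix, one frame per row.
#' @export
frame_signal <- function(w, cfg = feature_config()) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate != cfg$rate) stop("waveform rate does not match feature config")
  x <- w$samples
  nT <- frame_count(length(x), cfg)
  starts <- (seq_len(nT) - 1L) * cfg$hop_len
  idx <- outer(starts, seq_len(cfg$window_len), `+`)
  matrix(x[idx], nrow = nT)
}

#' Periodogram power-spectrum estimate of analysis frames
#'
#' Each (tapered) frame is zero-padded to `n_dft` points and transformed; the
#' one-sided power spectrum is `P[k] = |DFT(frame)[k]|^2 / window_len` for
#' `k = 0..n_dft/2` (no doubling of interior bins).
#'
#' @param frames a frames matrix from [frame_signal()], or a single frame
#'   vector of length `window_len`.
#' @param cfg a [feature_config()].
#' @return A `T x n_bins` non-negative matrix of power values.
#' @export
periodogram <- function(frames, cfg = feature_config()) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1L)
  if (ncol(frames) != cfg$window_len) stop("frames must have window_len columns")
  taper <- switch(cfg$window,
    rectangular = rep(1, cfg$window_len),
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(cfg$window_len) - 1L) / (cfg$window_len - 1L))
  )
  padded <- matrix(0, nrow = nrow(frames), ncol = cfg$n_dft)
  padded[, seq_len(cfg$window_len)] <- sweep(frames, 2L, taper, `*`)
  # mvfft works on columns; frames are rows
  spec <- stats::mvfft(t(padded))
  p <- (Mod(spec[seq_len(cfg$n_bins), , drop = FALSE])^2) / cfg$window_len
  t(p)
}

#' Mel scale and its inverse
#'
#' `mel(f) = 2595 log10(1 + f/700)`.
#'
#' @param f frequency in Hz.
#' @param m Mel value.
#' @return Mel value (`hz_to_mel`) or frequency in Hz (`mel_to_hz`).
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank
#'
#' `n_filters` triangular filters with peaks (height 1) at points evenly
#' spaced on the Mel axis between 0 Hz and the Nyquist frequency. Filter `j`
#' rises linearly from Mel point `j-1` to its peak at point `j` and falls to
#' zero at point `j+1`, evaluated at the DFT bin centre frequencies.
#'
#' @param cfg a [feature_config()].
#' @return An `n_filters x n_bins` non-negative matrix.
#' @export
mel_filterbank <- function(cfg = feature_config()) {
  nyquist <- cfg$rate / 2
  pts_mel <- seq(hz_to_mel(0), hz_to_mel(nyquist), length.out = cfg$n_filters + 2L)
  pts_hz <- mel_to_hz(pts_mel)
  bin_hz <- (seq_len(cfg$n_bins) - 1L) * cfg$rate / cfg$n_dft
  fb <- matrix(0, nrow = cfg$n_filters, ncol = cfg$n_bins)
  for (j in seq_len(cfg$n_filters)) {
    lo <- pts_hz[j]; mid <- pts_hz[j + 1L]; hi <- pts_hz[j + 2L]
    up <- (bin_hz - lo) / (mid - lo)
    down <- (hi - bin_hz) / (hi - mid)
    v <- pmax(0, pmin(up, down))
    fb[j, ] <- v / max(v)   # peak exactly 1 on the sampled bin grid
  }
  fb
}

#' Centre frequencies (Hz) of the Mel filterbank
#' @param cfg a [feature_config()].
#' @return Numeric vector of `n_filters` peak frequencies in Hz.
#' @export
mel_centers_hz <- function(cfg = feature_config()) {
  pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(cfg$rate / 2),
                       length.out = cfg$n_filters + 2L))
  pts[seq(2L, cfg$n_filters + 1L)]
}

# Orthonormal DCT-II matrix (n x n); row k gives coefficient k.
dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  j <- seq_len(n) - 1L
  m <- sqrt(2 / n) * cos(outer(k, j, function(k, j) pi * (j + 0.5) * k / n))
  m[1L, ] <- m[1L, ] / sqrt(2)
  m
}

#' Extract the 13-dimensional MFCC sequence from a waveform
#'
#' Runs the full front end: framing, periodogram, Mel filterbank, log, DCT-II
#' (orthonormal). Column 1 of the result is the natural-log total energy of
#' the raw frame (`ln(sum(frame^2))`, floored at `eps`); columns 2--13 are
#' cepstral coefficients 2--13.
#'
#' @param w a [waveform()] at the configured rate.
#' @param cfg a [feature_config()].
#' @return An object of class `mfcc`: list with `frames` (`T x 13` matrix),
#'   `hop_s`, `window_s` and `rate`.
#' @export
extract_mfcc <- function(w, cfg = feature_config()) {
  fr <- frame_signal(w, cfg)
  p <- periodogram(fr, cfg)
  fb <- mel_filterbank(cfg)
  e <- p %*% t(fb)                         # T x n_filters
  loge <- log(pmax(e, cfg$eps))
  d <- dct_matrix(cfg$n_filters)
  cep <- loge %*% t(d)                     # T x n_filters
  energy <- log(pmax(rowSums(fr^2), cfg$eps))
  out <- cbind(energy, cep[, cfg$keep, drop = FALSE])
  colnames(out) <- c("log_energy", paste0("c", cfg$keep))
  mfcc(out, hop_s = cfg$hop_ms / 1000, window_s = cfg$window_ms / 1000,
       rate = cfg$rate)
}

#' Construct an MFCC matrix object
#' @param frames `T x d` numeric matrix of feature vectors (time in rows).
#' @param hop_s hop between frames in seconds.
#' @param window_s analysis window length in seconds.
#' @param rate source audio sampling rate in Hz.
#' @return An object of class `mfcc`.
#' @export
mfcc <- function(frames, hop_s = 0.010, window_s = 0.025, rate = 8000) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 1L) stop("MFCC matrix must have at least one frame")
  if (!all(is.finite(frames))) stop("MFCC matrix contains non-finite values")
  structure(list(frames = frames, hop_s = hop_s, window_s = window_s,
                 rate = rate), class = "mfcc")
}

#' @export
print.mfcc <- function(x, ...) {
  cat(sprintf("<mfcc: %d frames x %d dims, hop %g ms>\n",
              nrow(x$frames), ncol(x$frames), 1000 * x$hop_s))
  invisible(x)
}

#' @export
dim.mfcc <- function(x) dim(x$frames)
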