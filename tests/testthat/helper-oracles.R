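# Independent reference implementations used as oracles. These deliberately
# share no code with the package: explicit DFT matrices instead of fft(),
# their own Mel map, filterbank and DCT built straight from the defining
# formulas, and loop-based metric computations.

# O(N^2) DFT via an explicit complex exponential matrix.
oracle_dft <- function(x, n) {
  xp <- c(x, rep(0, n - length(x)))
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% xp)
}

oracle_periodogram_frame <- function(frame, n_dft = 256) {
  X <- oracle_dft(frame, n_dft)
  (Mod(X[1:(n_dft / 2 + 1)])^2) / length(frame)
}

oracle_mel <- function(f) 2595 * log10(1 + f / 700)
oracle_mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

oracle_filterbank <- function(n_filters = 26, n_dft = 256, rate = 8000) {
  pts <- oracle_mel_inv(seq(0, oracle_mel(rate / 2), length.out = n_filters + 2))
  freqs <- (0:(n_dft / 2)) * rate / n_dft
  fb <- matrix(0, n_filters, length(freqs))
  for (j in 1:n_filters) {
    for (b in seq_along(freqs)) {
      f <- freqs[b]
      if (f >= pts[j] && f <= pts[j + 1]) {
        fb[j, b] <- (f - pts[j]) / (pts[j + 1] - pts[j])
      } else if (f > pts[j + 1] && f <= pts[j + 2]) {
        fb[j, b] <- (pts[j + 2] - f) / (pts[j + 2] - pts[j + 1])
      }
    }
    fb[j, ] <- fb[j, ] / max(fb[j, ])   # peak-1 normalization on the grid
  }
  fb
}

# Orthonormal DCT-II straight from the definition, elementwise.
oracle_dct2 <- function(v) {
  n <- length(v)
  sapply(1:n, function(k) {
    s <- sum(v * cos(pi * ((1:n) - 0.5) * (k - 1) / n))
    s * if (k == 1) sqrt(1 / n) else sqrt(2 / n)
  })
}

# Full 13-dim MFCC reference: loops over frames, no shared code paths.
# The explicit DFT matrix is built once per call and applied per frame.
oracle_mfcc <- function(samples, rate = 8000, eps = 1e-10) {
  win <- round(0.025 * rate); hop <- round(0.010 * rate)
  n_dft <- 256
  n_frames <- 1 + floor((length(samples) - win) / hop)
  fb <- oracle_filterbank(26, n_dft, rate)
  k <- 0:(n_dft - 1)
  W <- exp(-2i * pi * outer(k[1:(n_dft / 2 + 1)], k) / n_dft)
  out <- matrix(0, n_frames, 13)
  for (t in 1:n_frames) {
    fr <- samples[((t - 1) * hop + 1):((t - 1) * hop + win)]
    X <- W %*% c(fr, rep(0, n_dft - win))
    p <- (Mod(X)^2) / win
    e <- as.vector(fb %*% p)
    cep <- oracle_dct2(log(pmax(e, eps)))
    out[t, ] <- c(log(max(sum(fr^2), eps)), cep[2:13])
  }
  out
}

# Brute-force classification metrics from explicit confusion counts and an
# exhaustive threshold sweep for the AUCs (trapezoid over the step curve).
oracle_metrics <- function(y, scores, threshold = 0.5) {
  tp <- sum(y == 2 & scores > threshold); fp <- sum(y == 1 & scores > threshold)
  fn <- sum(y == 2 & scores <= threshold); tn <- sum(y == 1 & scores <= threshold)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- sapply(thr, function(th) sum(y == 2 & scores >= th) / sum(y == 2))
  fpr <- sapply(thr, function(th) sum(y == 1 & scores >= th) / sum(y == 1))
  prec <- sapply(thr, function(th) {
    n_called <- sum(scores >= th)
    if (n_called == 0) 1 else sum(y == 2 & scores >= th) / n_called
  })
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  prauc <- sum(diff(tpr) * (head(prec, -1) + tail(prec, -1)) / 2)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       accuracy = (tp + tn) / length(y),
       # 0-denominator convention: MCC of a degenerate confusion matrix is 0
       mcc = {
         den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
         if (den == 0) 0 else (tp * tn - fp * fn) / den
       },
       roc_auc = auc, pr_auc = prauc)
}

# Welch two-sample t statistic and p-value from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# Dominant frequency of a waveform by periodogram peak on the full signal.
oracle_peak_hz <- function(w) {
  n <- length(w$samples)
  sp <- Mod(fft(w$samples))^2
  half <- floor(n / 2)
  (which.max(sp[2:half])) * w$rate / n
}
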