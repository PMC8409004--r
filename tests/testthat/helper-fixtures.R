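# Small fixtures built in code at test time.

sine_waveform <- function(freq, dur_s = 1, rate = 8000, amp = 0.5) {
  t <- seq_len(dur_s * rate) / rate
  waveform(amp * sin(2 * pi * freq * t), rate)
}

random_mfcc <- function(n_frames, dim = 13, seed = 1) {
  set.seed(seed)
  mfcc(matrix(rnorm(n_frames * dim), n_frames, dim))
}

# Minimal segmentation fixture
seg_fixture <- function(...) {
  segmentation(data.frame(...))
}

# A tiny CNN (2 pooled blocks, 16 frames per position) for fast tests.
tiny_cnn <- function(seed = 1) {
  init_cnn_model(cnn_config(channels = c(4, 6, 8), n_pool_blocks = 2,
                            input_dim = 13), seed = seed)
}

# A tiny LSTM for fast tests.
tiny_lstm <- function(seed = 1) {
  init_lstm_model(lstm_config(segment_len = 50, step_group = 5,
                              hidden_dim = 8, mlp_hidden = 8, input_dim = 13),
                  seed = seed)
}

# Write a PCM16 WAV with arbitrary channel layout for read_wav tests.
write_pcm16 <- function(path, channel_matrix, rate) {
  x <- as.vector(channel_matrix)          # interleaved: channels in rows
  pcm <- as.integer(round(pmin(1, pmax(-1, x)) * 32767))
  n_ch <- nrow(channel_matrix)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2 * n_ch), con, size = 4, endian = "little")
  writeBin(as.integer(2 * n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(16), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  path
}
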