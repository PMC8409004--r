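#' 1-D CNN configuration
#'
#' The convolutional classifier stacks `n_blocks` blocks of two length-
#' preserving 1-D convolutions (kernel 3, stride 1, padding 1, ReLU after
#' each) over the MFCC time axis. The first `n_pool_blocks` blocks end in
#' max pooling with kernel 4 and stride 4, so each position surviving to the
#' top spans `4^n_pool_blocks` input frames. Global average pooling then
#' collapses the variable-length feature map to one vector per recording and
#' a linear classifier produces the two class logits. Because the classifier
#' is linear, applying it position-wise before the average yields a temporal
#' class-evidence (saliency) track whose mean is exactly the recording logit.
#'
#' @param channels integer vector of output channels per block.
#'   Default `c(16, 32, 32, 64, 64, 128, 128)`.
#' @param input_dim input channels (MFCC dimensionality). Default 13.
#' @param kernel convolution kernel size. Default 3 (only 3 supported).
#' @param pool max-pool kernel = stride. Default 4.
#' @param n_pool_blocks number of leading blocks that max-pool. The full
#'   model uses 6 (the default, giving 4096 frames, ~41 s at a 10 ms hop,
#'   per top position) or 7; smaller values are allowed for reduced models.
#' @param n_classes output classes. Default 2.
#' @return A `cnn_config` list with derived `frames_per_position`.
#' @export
cnn_config <- function(channels = c(16, 32, 32, 64, 64, 128, 128),
                       input_dim = 13, kernel = 3, pool = 4,
                       n_pool_blocks = 6, n_classes = 2) {
  if (kernel != 3) stop("only kernel size 3 is supported")
  if (n_pool_blocks < 1L) stop("n_pool_blocks must be >= 1")
  if (n_pool_blocks > length(channels)) {
    stop("n_pool_blocks cannot exceed the number of blocks")
  }
  structure(list(channels = as.integer(channels),
                 n_blocks = length(channels),
                 input_dim = as.integer(input_dim),
                 kernel = as.integer(kernel),
                 pool = as.integer(pool),
                 n_pool_blocks = as.integer(n_pool_blocks),
                 n_classes = as.integer(n_classes),
                 frames_per_position = as.integer(pool^n_pool_blocks)),
            class = "cnn_config")
}

#' Initialize a 1-D CNN model
#' @param cfg a [cnn_config()].
#' @param seed integer RNG seed for the weight initialization.
#' @return An object of class `cnn_model`.
#' @export
init_cnn_model <- function(cfg = cnn_config(), seed = 1L) {
  set.seed(seed)
  params <- list()
  c_in <- cfg$input_dim
  for (b in seq_len(cfg$n_blocks)) {
    c_out <- cfg$channels[b]
    for (l in 1:2) {
      fan <- c_in * cfg$kernel
      for (k in 1:3) {
        params[[sprintf("b%d.conv%d.W%d", b, l, k)]] <- init_mat(c_in, c_out, fan_in = fan)
      }
      params[[sprintf("b%d.conv%d.b", b, l)]] <- init_vec(c_out, fan_in = fan)
      c_in <- c_out
    }
  }
  params$cls.W <- init_mat(c_in, cfg$n_classes, fan_in = c_in)
  params$cls.b <- init_vec(cfg$n_classes, fan_in = c_in)
  structure(list(cfg = cfg, params = params, seed = seed),
            class = c("cnn_model", "vox_model"))
}

# kernel-3 conv / stride-k max-pool over rows; hot loops in src/nn_ops.cpp
conv1d_layer <- function(X, p, pre, apply_relu = TRUE) {
  conv1d_forward_cpp(X, p[[paste0(pre, ".W1")]], p[[paste0(pre, ".W2")]],
                     p[[paste0(pre, ".W3")]], p[[paste0(pre, ".b")]],
                     apply_relu)
}

conv1d_layer_backward <- function(X, dY, Yact, p, pre, g) {
  cb <- conv1d_backward_cpp(X, dY, Yact,
                            p[[paste0(pre, ".W1")]], p[[paste0(pre, ".W2")]],
                            p[[paste0(pre, ".W3")]])
  g[[paste0(pre, ".W1")]] <- g[[paste0(pre, ".W1")]] + cb$dW1
  g[[paste0(pre, ".W2")]] <- g[[paste0(pre, ".W2")]] + cb$dW2
  g[[paste0(pre, ".W3")]] <- g[[paste0(pre, ".W3")]] + cb$dW3
  g[[paste0(pre, ".b")]] <- g[[paste0(pre, ".b")]] + as.numeric(cb$db)
  list(dX = cb$dX, g = g)
}

maxpool_forward <- function(X, k) {
  out <- maxpool_forward_cpp(X, as.integer(k))
  list(Y = out$Y, src_row = out$src_row)
}

maxpool_backward <- function(pool, dY, n_rows_in) {
  maxpool_backward_cpp(pool$src_row, dY, as.integer(n_rows_in))
}

#' Forward pass of the 1-D CNN
#'
#' Inputs shorter than `frames_per_position` frames are right-zero-padded so
#' at least one pre-pool position exists; global average pooling then runs
#' over all surviving positions.
#'
#' @param m an [mfcc()] (or bare `T x input_dim` matrix).
#' @param model an [init_cnn_model()].
#' @param keep_cache keep intermediate activations (training use).
#' @return List with `prediction` (a `prediction` object), `prepool`
#'   (`L x C` pre-GAP feature map) and, if requested, `cache`.
#' @export
cnn_forward <- function(m, model, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  X <- if (inherits(m, "mfcc")) m$frames else as.matrix(m)
  if (nrow(X) < 1L) stop("empty MFCC matrix")
  if (nrow(X) < cfg$frames_per_position) {
    X <- rbind(X, matrix(0, cfg$frames_per_position - nrow(X), ncol(X)))
  }
  cache <- if (keep_cache) list(inputs = list(), acts = list(), pools = list()) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    for (l in 1:2) {
      pre <- sprintf("b%d.conv%d", b, l)
      if (keep_cache) cache$inputs[[pre]] <- X
      X <- conv1d_layer(X, p, pre)
      if (keep_cache) cache$acts[[pre]] <- X
    }
    if (b <= cfg$n_pool_blocks) {
      pool <- maxpool_forward(X, cfg$pool)
      if (keep_cache) cache$pools[[b]] <- pool
      X <- pool$Y
    }
  }
  prepool <- X                                   # L x C
  gap <- colMeans(prepool)
  logits <- drop(gap %*% p$cls.W) + p$cls.b
  if (!all(is.finite(logits))) stop("non-finite activations in CNN forward")
  if (keep_cache) {
    cache$prepool <- prepool
    cache$gap <- gap
  }
  list(prediction = as_prediction(logits), prepool = prepool, cache = cache)
}

# Backward from dlogits (length n_classes) for one recording.
cnn_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg; p <- model$params
  g <- zero_like(p)
  cache <- fwd$cache
  gap <- cache$gap
  g$cls.W <- g$cls.W + outer(gap, dlogits)
  g$cls.b <- g$cls.b + dlogits
  L <- nrow(cache$prepool)
  dX <- matrix(rep(drop(p$cls.W %*% dlogits) / L, each = L), nrow = L)
  for (b in rev(seq_len(cfg$n_blocks))) {
    if (b <= cfg$n_pool_blocks) {
      pool <- cache$pools[[b]]
      dX <- maxpool_backward(pool, dX,
                             n_rows_in = nrow(pool$src_row) * cfg$pool)
      # restore any remainder rows the pool dropped
      full_rows <- nrow(cache$acts[[sprintf("b%d.conv2", b)]])
      if (nrow(dX) < full_rows) {
        dX <- rbind(dX, matrix(0, full_rows - nrow(dX), ncol(dX)))
      }
    }
    for (l in 2:1) {
      pre <- sprintf("b%d.conv%d", b, l)
      cb <- conv1d_layer_backward(cache$inputs[[pre]], dX, cache$acts[[pre]],
                                  p, pre, g)
      dX <- cb$dX
      g <- cb$g
    }
  }
  g
}
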