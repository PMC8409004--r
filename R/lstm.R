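#' Hierarchical LSTM configuration
#'
#' The two-level LSTM digests arbitrarily long MFCC sequences: consecutive
#' frames are grouped into fixed-length segments, a low-level LSTM encodes
#' each segment (reading `step_group` concatenated frames per step) into its
#' final hidden state, and a high-level LSTM summarizes the sequence of
#' segment vectors into one recording-level vector that a small MLP maps to
#' class probabilities. Both levels use the same hidden dimension and zero
#' initial states; their weights are separate.
#'
#' @param segment_len frames per segment (no overlap). Default 2000.
#' @param step_group frames concatenated into one low-level input step.
#'   Default 10 (so each step input is `10 * input_dim` dimensional).
#' @param hidden_dim hidden-state dimension of both LSTM levels. Default 64.
#' @param mlp_hidden hidden layer width of the output MLP. Default 64.
#' @param n_classes number of output classes. Default 2.
#' @param input_dim dimensionality of each MFCC vector. Default 13.
#' @return An `lstm_config` list.
#' @export
lstm_config <- function(segment_len = 2000, step_group = 10, hidden_dim = 64,
                        mlp_hidden = 64, n_classes = 2, input_dim = 13) {
  if (segment_len %% step_group != 0) {
    stop("segment_len must be divisible by step_group")
  }
  if (hidden_dim <= 0) stop("hidden_dim must be positive")
  structure(list(segment_len = as.integer(segment_len),
                 step_group = as.integer(step_group),
                 hidden_dim = as.integer(hidden_dim),
                 mlp_hidden = as.integer(mlp_hidden),
                 n_classes = as.integer(n_classes),
                 input_dim = as.integer(input_dim),
                 step_dim = as.integer(step_group * input_dim)),
            class = "lstm_config")
}

#' Initialize a hierarchical LSTM model
#'
#' @param cfg an [lstm_config()].
#' @param seed integer RNG seed for the weight initialization.
#' @return An object of class `lstm_model` holding the flat parameter list.
#' @export
init_lstm_model <- function(cfg = lstm_config(), seed = 1L) {
  set.seed(seed)
  h <- cfg$hidden_dim
  params <- list(
    ll.W = init_mat(cfg$step_dim, 4L * h, fan_in = cfg$step_dim),
    ll.U = init_mat(h, 4L * h, fan_in = h),
    ll.b = init_vec(4L * h, fan_in = h),
    hl.W = init_mat(h, 4L * h, fan_in = h),
    hl.U = init_mat(h, 4L * h, fan_in = h),
    hl.b = init_vec(4L * h, fan_in = h),
    mlp.W1 = init_mat(h, cfg$mlp_hidden, fan_in = h),
    mlp.b1 = init_vec(cfg$mlp_hidden, fan_in = h),
    mlp.W2 = init_mat(cfg$mlp_hidden, cfg$n_classes, fan_in = cfg$mlp_hidden),
    mlp.b2 = init_vec(cfg$n_classes, fan_in = cfg$mlp_hidden)
  )
  structure(list(cfg = cfg, params = params, seed = seed),
            class = c("lstm_model", "vox_model"))
}

#' Group an MFCC matrix into low-level LSTM segments
#'
#' Frames are cut into consecutive `segment_len`-frame segments without
#' overlap; the trailing segment is zero-padded up to a multiple of
#' `step_group` frames. Within a segment each step input is the concatenation
#' of `step_group` consecutive frame vectors.
#'
#' @param m an [mfcc()] (or bare `T x input_dim` matrix).
#' @param cfg an [lstm_config()].
#' @return List of step matrices, each `n_steps x (step_group * input_dim)`.
#' @export
segment_mfcc <- function(m, cfg = lstm_config()) {
  x <- if (inherits(m, "mfcc")) m$frames else as.matrix(m)
  nT <- nrow(x)
  if (nT < 1L) stop("empty MFCC matrix")
  n_seg <- ceiling(nT / cfg$segment_len)
  lapply(seq_len(n_seg), function(i) {
    lo <- (i - 1L) * cfg$segment_len + 1L
    hi <- min(i * cfg$segment_len, nT)
    s <- x[lo:hi, , drop = FALSE]
    pad <- (cfg$step_group - nrow(s) %% cfg$step_group) %% cfg$step_group
    if (pad > 0L) s <- rbind(s, matrix(0, pad, ncol(s)))
    matrix(as.vector(t(s)), ncol = cfg$step_dim, byrow = TRUE)
  })
}

# ---- masked batched LSTM layer -------------------------------------------
#
# Runs one LSTM over a batch of sequences stored as a (B, D, T) array with
# per-sequence lengths `lens`; the state of a finished sequence is frozen, so
# the returned h equals each sequence's hidden state at its own last step.
# The time loop runs in compiled code (src/nn_ops.cpp).

lstm_layer_forward <- function(A, lens, W, U, b, keep_cache = FALSE) {
  out <- lstm_forward_cpp(A, as.integer(lens), W, U, b, keep_cache)
  list(h = out$h, cache = if (keep_cache) out else NULL, A = A, lens = lens)
}

lstm_layer_backward <- function(fwd, dH_last, W, U, need_dx = FALSE) {
  out <- lstm_backward_cpp(fwd$A, fwd$cache, dH_last, W, U, need_dx)
  list(dW = out$dW, dU = out$dU, db = as.numeric(out$db), dX = out$dX)
}

# Pack a list of step matrices (n_steps x D) into a (B, D, maxT) array.
pack_segments <- function(seg_list, D) {
  B <- length(seg_list)
  lens <- vapply(seg_list, nrow, integer(1))
  A <- array(0, dim = c(B, D, max(lens)))
  for (i in seq_len(B)) A[i, , seq_len(lens[i])] <- t(seg_list[[i]])
  list(A = A, lens = lens)
}

# ---- full hierarchical forward/backward ----------------------------------

# Forward pass for a batch of recordings; seg-level work is batched across
# the whole minibatch for speed. Returns per-recording logits and (optionally)
# every cache needed for backprop.
lstm_hier_forward <- function(model, mfcc_list, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  segs_per_rec <- lapply(mfcc_list, segment_mfcc, cfg = cfg)
  owner <- rep(seq_along(segs_per_rec), vapply(segs_per_rec, length, integer(1)))
  all_segs <- unlist(segs_per_rec, recursive = FALSE)
  packed <- pack_segments(all_segs, cfg$step_dim)
  low <- lstm_layer_forward(packed$A, packed$lens, p$ll.W, p$ll.U, p$ll.b,
                            keep_cache = keep_cache)
  n_rec <- length(mfcc_list)
  logits <- matrix(0, n_rec, cfg$n_classes)
  high <- vector("list", n_rec)
  mlp_cache <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    hv <- low$h[owner == r, , drop = FALSE]        # n_segs x H, in order
    Ahi <- array(0, dim = c(1L, cfg$hidden_dim, nrow(hv)))
    Ahi[1, , ] <- t(hv)
    hi <- lstm_layer_forward(Ahi, nrow(hv), p$hl.W, p$hl.U, p$hl.b,
                             keep_cache = keep_cache)
    hsum <- hi$h[1, ]
    z1 <- drop(hsum %*% p$mlp.W1) + p$mlp.b1
    a1 <- relu(z1)
    lg <- drop(a1 %*% p$mlp.W2) + p$mlp.b2
    if (!all(is.finite(lg))) {
      stop("non-finite activations in LSTM forward (recording ", r, ")")
    }
    logits[r, ] <- lg
    if (keep_cache) {
      high[[r]] <- hi
      mlp_cache[[r]] <- list(hsum = hsum, z1 = z1, a1 = a1)
    }
  }
  list(logits = logits, low = low, high = high, mlp = mlp_cache,
       owner = owner)
}

# Backward: dlogits is n_rec x n_classes. Returns flat grad list.
lstm_hier_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg; p <- model$params
  g <- zero_like(p)
  n_rec <- nrow(dlogits)
  dH_low <- matrix(0, nrow(fwd$low$h), cfg$hidden_dim)
  for (r in seq_len(n_rec)) {
    mc <- fwd$mlp[[r]]
    dlg <- dlogits[r, ]
    g$mlp.W2 <- g$mlp.W2 + outer(mc$a1, dlg)
    g$mlp.b2 <- g$mlp.b2 + dlg
    da1 <- drop(p$mlp.W2 %*% dlg)
    dz1 <- da1 * (mc$z1 > 0)
    g$mlp.W1 <- g$mlp.W1 + outer(mc$hsum, dz1)
    g$mlp.b1 <- g$mlp.b1 + dz1
    dhsum <- drop(p$mlp.W1 %*% dz1)
    hb <- lstm_layer_backward(fwd$high[[r]], matrix(dhsum, 1L),
                              p$hl.W, p$hl.U, need_dx = TRUE)
    g$hl.W <- g$hl.W + hb$dW
    g$hl.U <- g$hl.U + hb$dU
    g$hl.b <- g$hl.b + hb$db
    # dX is (1, H, n_segs); transpose back to segments-in-rows
    dH_low[fwd$owner == r, ] <- t(matrix(hb$dX[1, , ], nrow = cfg$hidden_dim))
  }
  lb <- lstm_layer_backward(fwd$low, dH_low, p$ll.W, p$ll.U, need_dx = FALSE)
  g$ll.W <- g$ll.W + lb$dW
  g$ll.U <- g$ll.U + lb$dU
  g$ll.b <- g$ll.b + lb$db
  g
}

#' Classify a recording with the hierarchical LSTM
#'
#' @param m an [mfcc()].
#' @param model an initialized or trained [init_lstm_model()].
#' @return A `prediction`: list with `probs` (named 2-vector summing to 1),
#'   `logits` and `predicted` (class index, 1 = negative class, 2 = DE;
#'   ties at probability 0.5 resolve to the negative class).
#' @export
lstm_forward <- function(m, model) {
  fwd <- lstm_hier_forward(model, list(m), keep_cache = FALSE)
  as_prediction(fwd$logits[1, ])
}

as_prediction <- function(logits, classes = c("neg", "DE")) {
  probs <- softmax(logits)
  names(probs) <- classes
  names(logits) <- classes
  pred <- if (probs[2L] > 0.5) 2L else 1L
  structure(list(probs = probs, logits = logits, predicted = pred),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("<prediction: P(DE) = %.4f -> class %s>\n",
              x$probs[2L], names(x$probs)[x$predicted]))
  invisible(x)
}
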