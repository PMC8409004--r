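#' Training configuration
#'
#' Both classifiers are trained with Adam (learning rate 1e-4, betas
#' (0.99, 0.999)) on minibatches of 4 variable-length recordings, minimizing
#' class-weighted cross-entropy. Class weights default to inverse class
#' frequency (dementia is the minority class in the cohorts this pipeline
#' targets). All randomness (shuffling) descends from `seed`.
#'
#' @param epochs number of passes over the training set.
#' @param lr Adam learning rate. Default `1e-4`.
#' @param betas Adam moment decay rates. Default `c(0.99, 0.999)`.
#' @param batch_size recordings per optimizer step. Default 4.
#' @param seed integer RNG seed.
#' @param class_weights `"inverse"` for inverse-frequency weights (normalized
#'   to mean 1 over samples), or a numeric 2-vector.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 8, lr = 1e-4, betas = c(0.99, 0.999),
                         batch_size = 4, seed = 1L,
                         class_weights = "inverse") {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), lr = lr, betas = betas,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 class_weights = class_weights),
            class = "train_config")
}

resolve_class_weights <- function(labels, spec, n_classes = 2L) {
  if (is.numeric(spec)) return(spec / mean(spec[labels]))
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0L)) stop("training set must contain both classes")
  w <- length(labels) / (n_classes * counts)
  w / mean(w[labels])
}

#' Train a classifier on featurized recordings
#'
#' @param model an [init_lstm_model()] or [init_cnn_model()].
#' @param features list of [mfcc()] objects (one per recording).
#' @param labels integer class labels, 1 = negative class, 2 = DE.
#' @param tc a [train_config()].
#' @param verbose print per-epoch mean loss.
#' @return List with the trained `model` and `loss_trace` (mean weighted
#'   cross-entropy per epoch) plus the run metadata (`lr`, `betas`, `seed`).
#' @export
train_model <- function(model, features, labels, tc = train_config(),
                        verbose = FALSE) {
  stopifnot(length(features) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("training set must contain at least two classes")
  }
  w_class <- resolve_class_weights(labels, tc$class_weights,
                                   model$cfg$n_classes)
  set.seed(tc$seed)
  state <- adam_init(model$params)
  n <- length(features)
  loss_trace <- numeric(tc$epochs)
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[b0:min(b0 + tc$batch_size - 1L, n)]
      bres <- batch_grads(model, features[idx], labels[idx], w_class[labels[idx]])
      ep_loss <- ep_loss + bres$loss_sum
      upd <- adam_step(model$params, bres$grads, state, lr = tc$lr,
                       beta1 = tc$betas[1], beta2 = tc$betas[2])
      model$params <- upd$params
      state <- upd$state
    }
    loss_trace[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, loss_trace[ep]))
  }
  list(model = model, loss_trace = loss_trace,
       meta = list(lr = tc$lr, betas = tc$betas, batch_size = tc$batch_size,
                   epochs = tc$epochs, seed = tc$seed, class_weights = w_class))
}

# Gradients of the mean weighted cross-entropy over one minibatch.
batch_grads <- function(model, features, labels, weights) {
  nb <- length(features)
  if (inherits(model, "lstm_model")) {
    fwd <- lstm_hier_forward(model, features, keep_cache = TRUE)
    dlogits <- matrix(0, nb, model$cfg$n_classes)
    loss_sum <- 0
    for (r in seq_len(nb)) {
      xe <- xent_grad(fwd$logits[r, ], labels[r], weights[r])
      loss_sum <- loss_sum + xe$loss
      dlogits[r, ] <- xe$dlogits / nb
    }
    grads <- lstm_hier_backward(model, fwd, dlogits)
  } else {
    grads <- NULL
    loss_sum <- 0
    for (r in seq_len(nb)) {
      fwd <- cnn_forward(features[[r]], model, keep_cache = TRUE)
      xe <- xent_grad(fwd$prediction$logits, labels[r], weights[r])
      loss_sum <- loss_sum + xe$loss
      grads <- grad_add(grads, cnn_backward(model, fwd, xe$dlogits / nb))
    }
  }
  list(grads = grads, loss_sum = loss_sum)
}

#' Predict a single recording with either model
#' @param model a trained `lstm_model` or `cnn_model`.
#' @param m an [mfcc()].
#' @return A `prediction` object.
#' @export
predict_recording <- function(model, m) {
  if (inherits(model, "lstm_model")) lstm_forward(m, model)
  else cnn_forward(m, model)$prediction
}
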