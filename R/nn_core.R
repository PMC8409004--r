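# Shared neural-net primitives: initialization, activations, softmax
# cross-entropy, and the Adam optimizer. Parameters are flat named lists of
# numeric arrays so the optimizer is structure-agnostic.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Uniform(-s, s) init with s = 1/sqrt(fan_in); draws from the current RNG
# stream so a single seed set by the caller fans out to every component.
init_mat <- function(nrow, ncol, fan_in = nrow) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

init_vec <- function(n, fan_in) {
  s <- 1 / sqrt(fan_in)
  stats::runif(n, -s, s)
}

#' Softmax over the last dimension of a vector or matrix rows
#' @param x numeric vector (one sample) or matrix (samples in rows) of logits.
#' @return Probabilities with the same shape; rows sum to 1.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1L, max))
    z / rowSums(z)
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

# Weighted cross-entropy loss and its gradient in the logits for one sample.
# y is the 1-based class index; returns list(loss, dlogits).
xent_grad <- function(logits, y, weight = 1) {
  p <- softmax(logits)
  loss <- -weight * log(max(p[y], 1e-12))
  d <- p * weight
  d[y] <- d[y] - weight
  list(loss = loss, dlogits = d, probs = p)
}

# Adam state for a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam update; grads must have the same names/shapes as params.
adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.99, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Elementwise sum of two grad lists (same structure).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

zero_like <- function(params) lapply(params, function(p) p * 0)
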