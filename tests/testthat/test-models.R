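test_that("segment grouping follows the 2000-frame / 10-step contract", {
  cfg <- lstm_config()
  s1 <- segment_mfcc(random_mfcc(2000), cfg)
  expect_length(s1, 1)
  expect_equal(nrow(s1[[1]]), 200)
  expect_equal(ncol(s1[[1]]), 130)

  s2 <- segment_mfcc(random_mfcc(4500), cfg)
  expect_length(s2, 3)
  expect_equal(vapply(s2, nrow, integer(1)), c(200L, 200L, 50L))

  s3 <- segment_mfcc(random_mfcc(5), cfg)
  expect_length(s3, 1)
  expect_equal(nrow(s3[[1]]), 1)

  # step inputs are the concatenation of 10 consecutive frame vectors,
  # checked against explicit index enumeration
  m <- random_mfcc(2430, seed = 2)
  segs <- segment_mfcc(m, cfg)
  expect_equal(segs[[1]][3, ], as.vector(t(m$frames[21:30, ])))
  expect_equal(segs[[2]][1, 1:13], m$frames[2001, ])
  # zero padding on the ragged tail (2430 frames -> second segment 430
  # frames -> 43 steps, no padding needed; 2005 -> pad 5)
  m2 <- random_mfcc(2005, seed = 3)
  segs2 <- segment_mfcc(m2, cfg)
  expect_equal(nrow(segs2[[2]]), 1)
  expect_equal(segs2[[2]][1, ], c(m2$frames[2001:2005, ] |> t() |> as.vector(),
                                  rep(0, 65)))
  expect_error(segment_mfcc(matrix(0, 0, 13), cfg), "empty")
})

test_that("LSTM forward is a valid, deterministic probability model", {
  model <- tiny_lstm(seed = 5)
  m <- random_mfcc(173, seed = 7)
  p1 <- lstm_forward(m, model)
  p2 <- lstm_forward(m, model)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-9)
  expect_true(all(p1$probs >= 0))
  expect_identical(p1$probs, p2$probs)
  # recording split across segment boundaries reproduces the same segments
  segs <- segment_mfcc(m, model$cfg)
  manual <- lapply(c(0, 50, 100, 150), function(off) {
    lo <- off + 1; hi <- min(off + 50, 173)
    m$frames[lo:hi, , drop = FALSE]
  })
  for (i in 1:4) {
    pad <- (5 - nrow(manual[[i]]) %% 5) %% 5
    mm <- rbind(manual[[i]], matrix(0, pad, 13))
    expect_equal(segs[[i]], matrix(as.vector(t(mm)), ncol = 65, byrow = TRUE))
  }
})

test_that("CNN pooling law L = max(1, floor(T / frames_per_position))", {
  model <- tiny_cnn(seed = 2)   # 2 pooled blocks -> 16 frames per position
  fpp <- model$cfg$frames_per_position
  expect_equal(fpp, 16L)
  for (nT in c(3L, 16L, 64L, 70L, sample(17:600, 6))) {
    fwd <- cnn_forward(random_mfcc(nT, seed = nT), model)
    expect_equal(nrow(fwd$prepool), max(1L, nT %/% fpp))
    expect_equal(sum(fwd$prediction$probs), 1, tolerance = 1e-9)
  }
})

test_that("full-size CNN reduces 4096 frames to one position", {
  cfg <- cnn_config()
  expect_equal(cfg$frames_per_position, 4096L)
  model <- init_cnn_model(cnn_config(channels = c(2, 2, 2, 2, 2, 2, 2)), seed = 1)
  fwd <- cnn_forward(random_mfcc(4096, seed = 1), model)
  expect_equal(nrow(fwd$prepool), 1L)
  fwd2 <- cnn_forward(random_mfcc(16384, seed = 2), model)
  expect_equal(nrow(fwd2$prepool), 4L)
})

test_that("GAP and the linear classifier commute (saliency foundation)", {
  model <- tiny_cnn(seed = 9)
  for (s in 1:5) {
    m <- random_mfcc(sample(20:500, 1), seed = s)
    fwd <- cnn_forward(m, model)
    pos_logits <- sweep(fwd$prepool %*% model$params$cls.W, 2,
                        model$params$cls.b, `+`)
    expect_lt(max(abs(colMeans(pos_logits) - fwd$prediction$logits)), 1e-5)
  }
})

test_that("all trainable parameters receive gradients on a random batch", {
  lm <- tiny_lstm(seed = 1)
  feats <- lapply(1:4, function(i) random_mfcc(120, seed = i))
  b <- voxcog:::batch_grads(lm, feats, c(1L, 2L, 1L, 2L), rep(1, 4))
  for (nm in names(b$grads)) {
    expect_gt(max(abs(b$grads[[nm]])), 0, label = paste("lstm grad", nm))
  }
  cm <- tiny_cnn(seed = 1)
  b2 <- voxcog:::batch_grads(cm, feats, c(1L, 2L, 1L, 2L), rep(1, 4))
  for (nm in names(b2$grads)) {
    expect_gt(max(abs(b2$grads[[nm]])), 0, label = paste("cnn grad", nm))
  }
})

test_that("gradients match finite differences on tiny models", {
  lcfg <- lstm_config(segment_len = 20, step_group = 5, hidden_dim = 4,
                      mlp_hidden = 3, input_dim = 3)
  set.seed(42)
  m <- mfcc(matrix(rnorm(33 * 3), 33, 3))
  model <- init_lstm_model(lcfg, seed = 7)
  loss_of <- function(mod) {
    fwd <- voxcog:::lstm_hier_forward(mod, list(m), keep_cache = TRUE)
    voxcog:::xent_grad(fwd$logits[1, ], 2L, 1.3)
  }
  r <- loss_of(model)
  fwd <- voxcog:::lstm_hier_forward(model, list(m), keep_cache = TRUE)
  g <- voxcog:::lstm_hier_backward(model, fwd, matrix(r$dlogits, 1))
  eps <- 1e-6
  for (nm in names(model$params)) {
    np <- length(model$params[[nm]])
    idx <- sample(np, min(3L, np))
    for (i in idx) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm2 <- model; mm2$params[[nm]][i] <- mm2$params[[nm]][i] - eps
      num <- (loss_of(mp)$loss - loss_of(mm2)$loss) / (2 * eps)
      expect_lt(abs(g[[nm]][i] - num), 5e-3 * max(1, abs(num)))
    }
  }
  cm <- init_cnn_model(cnn_config(channels = c(4, 5), n_pool_blocks = 2,
                                  input_dim = 3), seed = 3)
  m2 <- mfcc(matrix(rnorm(40 * 3), 40, 3))
  loss_of2 <- function(mod) {
    fwd <- cnn_forward(m2, mod, keep_cache = TRUE)
    voxcog:::xent_grad(fwd$prediction$logits, 1L, 0.8)
  }
  fwd2 <- cnn_forward(m2, cm, keep_cache = TRUE)
  g2 <- voxcog:::cnn_backward(cm, fwd2, loss_of2(cm)$dlogits)
  for (nm in names(cm$params)) {
    np <- length(cm$params[[nm]])
    idx <- sample(np, min(3L, np))
    for (i in idx) {
      mp <- cm; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm3 <- cm; mm3$params[[nm]][i] <- mm3$params[[nm]][i] - eps
      num <- (loss_of2(mp)$loss - loss_of2(mm3)$loss) / (2 * eps)
      expect_lt(abs(g2[[nm]][i] - num), 5e-3 * max(1, abs(num)))
    }
  }
})

test_that("training fits separable toy data and is seed-deterministic", {
  set.seed(31)
  feats <- c(lapply(1:6, function(i) mfcc(matrix(rnorm(80 * 13, mean = 1.5), 80, 13))),
             lapply(1:6, function(i) mfcc(matrix(rnorm(80 * 13, mean = -1.5), 80, 13))))
  y <- rep(c(2L, 1L), each = 6)
  tc <- train_config(epochs = 20, lr = 5e-3, seed = 9)
  fit <- train_model(tiny_lstm(seed = 2), feats, y, tc)
  expect_lt(fit$loss_trace[20], fit$loss_trace[1])
  acc <- mean(vapply(seq_along(feats), function(i)
    predict_recording(fit$model, feats[[i]])$predicted == y[i], logical(1)))
  expect_equal(acc, 1.0)
  expect_equal(fit$meta$lr, 5e-3)
  fit2 <- train_model(tiny_lstm(seed = 2), feats, y, tc)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  expect_error(train_model(tiny_lstm(), feats, rep(1L, 12), tc), "two classes")
})

test_that("the default optimizer settings follow the training recipe", {
  tc <- train_config()
  expect_equal(tc$lr, 1e-4)
  expect_equal(tc$betas, c(0.99, 0.999))
  expect_equal(tc$batch_size, 4L)
})
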