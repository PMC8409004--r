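test_that("mean of the raw saliency track equals the DE logit", {
  model <- tiny_cnn(seed = 3)
  for (s in 1:5) {
    nT <- sample(30:400, 1)
    m <- random_mfcc(nT, seed = s + 100)
    dur <- nT * 0.010
    tr <- compute_saliency(model, m, dur)
    expect_lt(abs(mean(tr$raw) - tr$logit_de), 1e-5)
  }
})

test_that("per-second expansion matches a brute-force span oracle", {
  model <- tiny_cnn(seed = 11)
  nT <- 230                                    # 14 positions of 16 frames
  m <- random_mfcc(nT, seed = 42)
  dur <- nT * 0.010
  tr <- compute_saliency(model, m, dur)
  expect_equal(length(tr$per_second), ceiling(dur))
  expect_equal(tr$stride_s, 16 * 0.010)
  # oracle: assign each second to the position whose span contains it
  for (s in seq_len(length(tr$per_second))) {
    pos <- min(length(tr$raw), max(1, floor((s - 1) / tr$stride_s) + 1))
    expect_equal(tr$per_second[s], tr$raw[pos])
  }
  expect_true(all(tr$per_second %in% tr$raw))
})

test_that("single-position tracks give a constant per-second vector", {
  model <- tiny_cnn(seed = 4)
  m <- random_mfcc(10, seed = 1)     # < 16 frames -> padded, L = 1
  tr <- compute_saliency(model, m, 0.10)
  expect_equal(length(unique(tr$per_second)), 1L)
})

test_that("SAF reproduces the worked example and its complement law", {
  seg <- seg_fixture(test_name = "Boston Naming Test", start_s = 0, end_s = 100)
  track <- list(per_second = c(rep(1, 90), rep(-1, 10)))
  expect_equal(unname(saf(track, seg, "+")["Boston Naming Test"]), 0.90)
  expect_equal(unname(saf(track, seg, "-")["Boston Naming Test"]), 0.10)

  # all-positive track
  track2 <- list(per_second = rep(0.5, 200))
  seg2 <- seg_fixture(test_name = c("A", "B"), start_s = c(0, 120),
                      end_s = c(100, 180))
  expect_equal(unname(saf(track2, seg2, "+")), c(1, 1))
  expect_equal(unname(saf(track2, seg2, "-")), c(0, 0))

  # complementarity on random tracks/segmentations
  set.seed(19)
  for (r in 1:5) {
    track3 <- list(per_second = rnorm(300))
    seg3 <- seg_fixture(test_name = c("A", "B", "C"),
                        start_s = c(0, 110.4, 201.7),
                        end_s = c(100.2, 200.1, 290))
    sp <- saf(track3, seg3, "+"); sn <- saf(track3, seg3, "-")
    expect_equal(unname(sp + sn[names(sp)]), rep(1, 3))
    expect_true(all(sp >= 0 & sp <= 1))
  }
})

test_that("SAF aggregation uses TP/TN only, with the n = 1 sd convention", {
  seg <- seg_fixture(test_name = "BNT", start_s = 0, end_s = 100)
  mk <- function(frac_pos, truth, predicted) {
    list(track = list(per_second = c(rep(1, frac_pos * 100),
                                     rep(-1, 100 - frac_pos * 100))),
         seg = seg, truth = truth, predicted = predicted)
  }
  res <- list(mk(0.9, 2L, 2L),          # TP, SAF+ = 0.9
              mk(0.8, 2L, 2L),          # TP, SAF+ = 0.8... then mean 0.85
              mk(0.2, 1L, 1L),          # TN, SAF- = 0.8
              mk(0.9, 2L, 1L),          # FN: excluded
              mk(0.1, 1L, 2L))          # FP: excluded
  tab <- aggregate_saf(res, min_n = 1)$main
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_pos, 2)
  expect_equal(tab$n_neg, 1)
  expect_equal(tab$saf_pos_mean, mean(c(0.9, 0.8)))
  expect_equal(tab$saf_pos_sd, sd(c(0.9, 0.8)))
  expect_equal(tab$saf_neg_mean, 0.8)
  expect_equal(tab$saf_neg_sd, 0)       # single TN: sd convention 0

  # two TPs with SAF+ 0.8 and 1.0: mean 0.9, sd by hand
  res2 <- list(mk(0.8, 2L, 2L), mk(1.0, 2L, 2L))
  tab2 <- aggregate_saf(res2, min_n = 1)$main
  expect_equal(tab2$saf_pos_mean, 0.9)
  expect_equal(tab2$saf_pos_sd, sqrt(((0.8 - 0.9)^2 + (1 - 0.9)^2) / 1))

  # low-n routing
  split3 <- aggregate_saf(res, min_n = 10)
  expect_equal(nrow(split3$main), 0)
  expect_equal(nrow(split3$low_n), 1)
  expect_warning(aggregate_saf(list(mk(0.9, 2L, 1L))), "no true-positive")
})
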