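tl <- function(...) {
  rows <- list(...)
  data.frame(diagnosis_date = as.Date(vapply(rows, `[[`, "", 1)),
             status = vapply(rows, `[[`, "", 2))
}

test_that("the 180-day labeling rule maps constructed cases correctly", {
  rd <- as.Date("2015-06-01")
  # diagnosis after recording within the window
  expect_equal(assign_label(rd, tl(c("2015-09-09", "DE"))), "DE")   # +100 d
  # sole NC diagnosis beyond the window
  expect_equal(assign_label(rd, tl(c("2015-12-18", "NC"))), "NC")   # +200 d
  # sole non-NC diagnosis beyond the window
  expect_equal(assign_label(rd, tl(c("2015-12-18", "DE"))), "UNLABELED")
  expect_equal(assign_label(rd, tl(c("2015-12-18", "MCI"))), "UNLABELED")
  # diagnosis before the recording always eligible, however old
  expect_equal(assign_label(rd, tl(c("2010-01-01", "MCI"))), "MCI")
  # closest of several eligible wins
  expect_equal(assign_label(rd, tl(c("2015-01-01", "NC"),
                                   c("2015-05-30", "MCI"),
                                   c("2015-08-01", "DE"))), "MCI")
  # nearer future diagnosis inside window beats farther past one
  expect_equal(assign_label(rd, tl(c("2015-02-01", "NC"),
                                   c("2015-06-10", "DE"))), "DE")
  # boundary: exactly 180 days after is within the window
  expect_equal(assign_label(rd, tl(c("2015-11-28", "DE"))), "DE")
  # 181 days after, non-NC -> unlabeled
  expect_equal(assign_label(rd, tl(c("2015-11-29", "DE"))), "UNLABELED")
  # equidistant before/after: prefer the one on/before
  expect_equal(assign_label(rd, tl(c("2015-05-22", "NC"),
                                   c("2015-06-11", "DE"))), "NC")
  # diagnosis on the recording date wins outright
  expect_equal(assign_label(rd, tl(c("2015-06-01", "DE"),
                                   c("2015-06-02", "NC"))), "DE")
  # beyond-window NC only applies to the closest entry
  expect_equal(assign_label(rd, tl(c("2015-12-18", "DE"),
                                   c("2016-06-01", "NC"))), "UNLABELED")
  expect_error(assign_label(rd, tl()[0, ]), "empty")
})

test_that("every (date, timeline) input maps to exactly one label", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    timeline <- data.frame(
      diagnosis_date = as.Date("2014-01-01") + sort(sample(0:1000, n)),
      status = sample(c("NC", "MCI", "DE"), n, replace = TRUE))
    lab <- assign_label(as.Date("2015-01-01") + sample(0:500, 1), timeline)
    expect_true(lab %in% c("NC", "MCI", "DE", "UNLABELED"))
  }
})

test_that("splits are participant-disjoint and balanced", {
  ids <- sprintf("P%03d", 1:101)
  sp <- make_splits(ids, k = 5, test_fraction = 1 / 101, seed = 3)
  expect_length(sp$test_participants, 1)
  expect_equal(sort(vapply(sp$folds, length, integer(1))), rep(20L, 5))
  # determinism
  sp2 <- make_splits(ids, k = 5, test_fraction = 1 / 101, seed = 3)
  expect_identical(sp, sp2)
  expect_error(make_splits(ids[1:4], k = 5, test_fraction = 0), "folds")
})

test_that("split disjointness holds across 100 random seeds", {
  ids <- sprintf("P%02d", 1:37)
  for (seed in 1:100) {
    sp <- make_splits(ids, k = 5, test_fraction = 0.2, seed = seed)
    all_sets <- c(list(sp$test_participants), sp$folds)
    pooled <- unlist(all_sets)
    expect_equal(sort(pooled), sort(ids))        # cover everything
    expect_equal(anyDuplicated(pooled), 0L)      # brute-force disjointness
  }
})

test_that("segment extraction honours length, bounds and determinism", {
  m <- random_mfcc(40000, seed = 5)       # ~6.7 min
  set.seed(2)
  s5 <- extract_segment(m, 5)
  expect_equal(nrow(s5$mfcc$frames), 30000)
  expect_false(s5$truncated)
  expect_true(s5$start_frame >= 1 &&
                s5$start_frame + 30000 - 1 <= 40000)
  expect_equal(s5$mfcc$frames,
               m$frames[s5$start_frame:(s5$start_frame + 29999), ])
  s15 <- extract_segment(m, 15)
  expect_true(s15$truncated)
  expect_equal(nrow(s15$mfcc$frames), 40000)
  set.seed(9); a <- extract_segment(m, 5)$start_frame
  set.seed(9); b <- extract_segment(m, 5)$start_frame
  expect_equal(a, b)
})

test_that("metrics match the brute-force oracle on random score sets", {
  set.seed(13)
  for (r in 1:100) {
    n <- sample(7:25, 1)
    y <- c(1L, 2L, sample(1:2, n - 2, replace = TRUE))  # both classes present
    scores <- round(runif(n), sample(c(1, 2, 7), 1))    # induce score ties
    got <- compute_metrics(y, scores)
    want <- oracle_metrics(y, scores)
    for (k in names(want)) {
      expect_equal(got[[k]], want[[k]], tolerance = 1e-10,
                   label = paste(k, "rep", r))
    }
    expect_equal(got$balanced_accuracy,
                 (got$sensitivity + got$specificity) / 2)
    expect_true(got$mcc >= -1 && got$mcc <= 1)
  }
})

test_that("perfect separation gives AUC = 1 and MCC = 1", {
  y <- c(1L, 1L, 1L, 2L, 2L)
  s <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  m <- compute_metrics(y, s)
  expect_equal(m$roc_auc, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$pr_auc, 1)
  expect_error(compute_metrics(rep(2L, 4), runif(4)), "both classes")
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (r in 1:10) {
    y <- c(1L, 2L, sample(1:2, 30, replace = TRUE))
    s <- round(runif(32), 2)
    got <- roc_auc(y, s)
    want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<", levels = c(1, 2))))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(37)
  aucs <- replicate(40, {
    y <- sample(rep(1:2, each = 25))
    roc_auc(y, runif(50))
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("fold summaries use the sample sd", {
  fm <- lapply(c(0.6, 0.7, 0.8), function(a) {
    m <- compute_metrics(c(1L, 1L, 2L, 2L), c(0.1, 0.4, 0.6, 0.9))
    m$accuracy <- a
    m
  })
  s <- summarize_metrics(fm)
  expect_equal(unname(s$accuracy["mean"]), 0.7)
  expect_equal(unname(s$accuracy["sd"]), sd(c(0.6, 0.7, 0.8)))
})

test_that("duration comparisons match the Welch oracle and star codes", {
  set.seed(41)
  d <- data.frame(
    test_name = "BNT",
    group = rep(c("NC", "MCI", "DE"), each = 30),
    duration_s = c(rnorm(30, 406, 50), rnorm(30, 321, 50), rnorm(30, 611, 60)))
  tab <- duration_stats(d)
  nc_de <- tab[tab$group_a == "NC" & tab$group_b == "DE", ]
  ora <- oracle_welch(d$duration_s[d$group == "NC"],
                      d$duration_s[d$group == "DE"])
  expect_equal(nc_de$t, ora$t, tolerance = 1e-10)
  expect_equal(nc_de$p, ora$p, tolerance = 1e-10)
  expect_equal(nc_de$stars, "***")
  de_nde <- tab[tab$group_b == "NDE", ]
  ora2 <- oracle_welch(d$duration_s[d$group == "DE"],
                       d$duration_s[d$group != "DE"])
  expect_equal(de_nde$t, ora2$t, tolerance = 1e-10)

  # identical samples -> t = 0, n.s.
  d2 <- data.frame(test_name = "X", group = rep(c("NC", "DE"), each = 5),
                   duration_s = rep(c(3, 4, 5, 6, 7), 2))
  tab2 <- duration_stats(d2, pairs = list(c("NC", "DE")))
  expect_equal(tab2$t, 0)
  expect_equal(tab2$stars, "n.s.")

  # extreme separation -> ***
  d3 <- data.frame(test_name = "X", group = rep(c("NC", "DE"), each = 30),
                   duration_s = c(rnorm(30, 10, 0.1), rnorm(30, 1000, 0.1)))
  expect_equal(duration_stats(d3, pairs = list(c("NC", "DE")))$stars, "***")

  # insufficient n -> not computable
  d4 <- data.frame(test_name = "X", group = c("NC", "DE", "DE"),
                   duration_s = c(5, 6, 7))
  expect_equal(duration_stats(d4, pairs = list(c("NC", "DE")))$stars, "n.c.")
})

test_that("balanced accuracy identity holds on the printed metric triple", {
  # internal consistency of a reported (sensitivity, specificity,
  # balanced accuracy) triple under the defining identity
  expect_equal(round((0.470 + 0.824) / 2, 3), 0.647)
})
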