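#' Assign a cognitive label to a recording from a diagnosis timeline
#'
#' Among diagnoses dated on/before the recording or within 180 days after it,
#' the status of the one closest in absolute days is returned (an equidistant
#' before/after tie prefers the diagnosis on/before the recording, anchoring
#' on status at the time of testing). If the only diagnoses are more than 180
#' days after the recording, the closest one is used only when it is NC
#' (normal cognition persists backwards); otherwise the recording is
#' `UNLABELED` and excluded from modeling.
#'
#' @param recording_date a `Date` (or ISO-8601 string).
#' @param timeline data frame with `diagnosis_date` (`Date`) and `status`
#'   (`NC`/`MCI`/`DE`), as produced by [read_timelines()].
#' @param window_days look-ahead window in days. Default 180.
#' @return One of `"NC"`, `"MCI"`, `"DE"`, `"UNLABELED"`.
#' @export
assign_label <- function(recording_date, timeline, window_days = 180) {
  if (is.null(timeline) || nrow(timeline) == 0L) stop("empty diagnosis timeline")
  rd <- as.Date(recording_date)
  delta <- as.numeric(timeline$diagnosis_date - rd)   # days; >0 means after
  eligible <- delta <= window_days
  if (any(eligible)) {
    cand <- which(eligible)
    best <- cand[order(abs(delta[cand]), delta[cand])][1L]  # tie -> on/before
    return(timeline$status[best])
  }
  closest <- which.min(delta)   # all deltas > window_days here
  if (timeline$status[closest] == "NC") "NC" else "UNLABELED"
}

#' Participant-level train/test and cross-validation split
#'
#' A fraction of participants (with all their recordings) is held out for
#' independent testing; the remainder is partitioned into `k` folds balanced
#' in participant count within one. All grouping is at the participant level
#' so no participant's recordings straddle two partitions.
#'
#' @param participants character vector of unique participant ids.
#' @param k number of cross-validation folds. Default 5.
#' @param test_fraction fraction of participants held out. Default 0.2.
#' @param seed integer RNG seed.
#' @return A `fold_split`: list with `test_participants` and `folds` (list of
#'   `k` character vectors).
#' @export
make_splits <- function(participants, k = 5, test_fraction = 0.2, seed = 1L) {
  participants <- unique(as.character(participants))
  set.seed(seed)
  n <- length(participants)
  n_test <- round(n * test_fraction)
  shuffled <- sample(participants)
  test_participants <- shuffled[seq_len(n_test)]
  rest <- shuffled[setdiff(seq_len(n), seq_len(n_test))]
  if (k > length(rest)) stop("not enough participants for ", k, " folds")
  fold_id <- rep_len(seq_len(k), length(rest))
  folds <- split(rest, fold_id)
  names(folds) <- NULL
  structure(list(test_participants = test_participants, folds = folds,
                 k = k, seed = seed), class = "fold_split")
}

#' Extract a random contiguous short segment from a featurized recording
#'
#' Mirrors short-segment evaluation: a single contiguous window of
#' `length_min` minutes of frames at a uniformly random admissible start.
#' Recordings shorter than the request return whole (flagged).
#'
#' @param m an [mfcc()].
#' @param length_min requested length in minutes (e.g. 5, 10, 15).
#' @return List with `mfcc` (the sub-sequence), `start_frame` and
#'   `truncated` (`TRUE` when the whole recording was returned).
#' @export
extract_segment <- function(m, length_min) {
  want <- as.integer(round(length_min * 60 / m$hop_s))
  nT <- nrow(m$frames)
  if (nT <= want) {
    return(list(mfcc = m, start_frame = 1L, truncated = TRUE))
  }
  start <- sample.int(nT - want + 1L, 1L)
  sub <- mfcc(m$frames[start:(start + want - 1L), , drop = FALSE],
              hop_s = m$hop_s, window_s = m$window_s, rate = m$rate)
  list(mfcc = sub, start_frame = start, truncated = FALSE)
}

#' Binary classification metric suite for one fold
#'
#' Computes the confusion-matrix metrics at a fixed threshold plus ROC and
#' precision-recall AUCs by trapezoidal integration over the exact step
#' curves traced by sweeping the score threshold.
#'
#' @param y_true integer labels, 1 = negative class, 2 = DE (positive).
#' @param scores DE probabilities (or any monotone score).
#' @param threshold decision threshold on the score. Default 0.5; a score
#'   exactly at the threshold resolves to the negative class.
#' @return Named list: `accuracy`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `weighted_f1`, `mcc`, `roc_auc`,
#'   `pr_auc`, plus the confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y <- as.integer(y_true)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to compute AUCs")
  }
  pred <- ifelse(scores > threshold, 2L, 1L)
  tp <- sum(pred == 2L & y == 2L)
  tn <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 2L & y == 1L)
  fn <- sum(pred == 1L & y == 2L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  # per-class F1 weighted by support
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_neg <- spec
  f1_neg <- if (prec_neg + rec_neg > 0) 2 * prec_neg * rec_neg / (prec_neg + rec_neg) else 0
  n_pos <- sum(y == 2L); n_neg <- sum(y == 1L)
  wf1 <- (n_pos * f1 + n_neg * f1_neg) / (n_pos + n_neg)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den else 0
  list(accuracy = (tp + tn) / length(y),
       balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1, weighted_f1 = wf1, mcc = mcc,
       roc_auc = roc_auc(y, scores), pr_auc = pr_auc(y, scores),
       tp = tp, tn = tn, fp = fp, fn = fn)
}

# ROC / PR step curves over all distinct score thresholds.
roc_points <- function(y, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  pos <- cumsum(y == 2L)
  neg <- cumsum(y == 1L)
  # collapse ties: keep the last point of each distinct score
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, pos[keep] / sum(y == 2L))
  fpr <- c(0, neg[keep] / sum(y == 1L))
  list(tpr = tpr, fpr = fpr,
       prec = c(1, (pos / pmax(pos + neg, 1))[keep]),
       rec = c(0, pos[keep] / sum(y == 2L)))
}

#' Area under the ROC curve (trapezoidal)
#' @param y integer labels (1 negative, 2 positive).
#' @param scores scores for the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y, scores) {
  pts <- roc_points(as.integer(y), scores)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Area under the precision-recall curve (trapezoidal)
#' @inheritParams roc_auc
#' @return PR AUC in \[0, 1\].
#' @export
pr_auc <- function(y, scores) {
  pts <- roc_points(as.integer(y), scores)
  sum(diff(pts$rec) * (utils::head(pts$prec, -1) + utils::tail(pts$prec, -1)) / 2)
}

#' Mean and standard deviation of fold metrics
#' @param fold_metrics list of [compute_metrics()] results (one per fold).
#' @return Named list of `c(mean, sd)` pairs (sample sd, `n - 1`).
#' @export
summarize_metrics <- function(fold_metrics) {
  nm <- c("accuracy", "balanced_accuracy", "sensitivity", "specificity",
          "precision", "f1", "weighted_f1", "mcc", "roc_auc", "pr_auc")
  out <- lapply(nm, function(k) {
    v <- vapply(fold_metrics, function(fm) fm[[k]], numeric(1))
    c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
  })
  stats::setNames(out, nm)
}

#' Pairwise test-duration comparisons by cognitive group
#'
#' For each neuropsychological test, compares mean administered durations
#' between group pairs (NC-MCI, MCI-DE, NC-DE, DE-NDE by default) with a
#' two-sample t-test (Welch by default) and attaches the conventional star
#' code (* p<0.05, ** p<0.01, *** p<0.001, n.s. otherwise).
#'
#' @param durations data frame with columns `test_name`, `group` (NC, MCI,
#'   DE; NDE is derived as NC + MCI) and `duration_s`.
#' @param pairs list of 2-vectors of group names to compare.
#' @param var_equal `FALSE` (Welch, default) or `TRUE` (Student's).
#' @return Data frame with per-test, per-pair group means/sds, `t`, `p` and
#'   `stars`; pairs with fewer than 2 observations in a group are marked
#'   not-computable (`NA` statistics, stars `"n.c."`).
#' @export
duration_stats <- function(durations,
                           pairs = list(c("NC", "MCI"), c("MCI", "DE"),
                                        c("NC", "DE"), c("DE", "NDE")),
                           var_equal = FALSE) {
  stopifnot(all(c("test_name", "group", "duration_s") %in% names(durations)))
  grp <- function(df, gname) {
    if (gname == "NDE") df$duration_s[df$group %in% c("NC", "MCI")]
    else df$duration_s[df$group == gname]
  }
  rows <- list()
  for (tn in unique(durations$test_name)) {
    df <- durations[durations$test_name == tn, , drop = FALSE]
    for (pr in pairs) {
      a <- grp(df, pr[1]); b <- grp(df, pr[2])
      if (length(a) >= 2L && length(b) >= 2L &&
          (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        tt <- stats::t.test(a, b, var.equal = var_equal)
        t_stat <- unname(tt$statistic); p <- tt$p.value
      } else if (length(a) >= 2L && length(b) >= 2L) {
        t_stat <- 0; p <- 1       # identical constant groups
      } else {
        t_stat <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        test_name = tn, group_a = pr[1], group_b = pr[2],
        mean_a = mean(a), sd_a = if (length(a) > 1) stats::sd(a) else NA_real_,
        mean_b = mean(b), sd_b = if (length(b) > 1) stats::sd(b) else NA_real_,
        n_a = length(a), n_b = length(b), t = t_stat, p = p,
        stars = star_code(p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

star_code <- function(p) {
  if (is.na(p)) return("n.c.")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}
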