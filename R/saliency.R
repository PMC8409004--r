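#' Temporal DE[+] saliency track of a recording
#'
#' Applies the CNN's linear classifier position-wise (bias included) to the
#' feature map right before global average pooling and keeps the DE row,
#' giving one class-evidence value per surviving temporal position. Because
#' global average pooling and the classifier commute, the mean of the raw
#' track equals the recording-level DE logit exactly (up to float rounding).
#' The raw track is expanded to one value per second by span membership: each
#' second belongs to the position whose temporal span contains it (clamped at
#' the edges), which is nearest-neighbour interpolation for uniform spans.
#'
#' @param model a trained `cnn_model`.
#' @param m an [mfcc()].
#' @param duration_s recording duration in seconds; must agree with the frame
#'   count within one position span.
#' @param include_bias include the classifier bias in each position score
#'   (default `TRUE`, which preserves the mean = logit identity).
#' @return A `saliency_track`: list with `raw` (length-L vector), `stride_s`
#'   (seconds per position) and `per_second` (length `ceiling(duration_s)`).
#' @export
compute_saliency <- function(model, m, duration_s, include_bias = TRUE) {
  stopifnot(inherits(model, "cnn_model"))
  nT <- nrow(if (inherits(m, "mfcc")) m$frames else m)
  hop_s <- if (inherits(m, "mfcc")) m$hop_s else 0.010
  stride_s <- model$cfg$frames_per_position * hop_s
  # frame count implies the duration up to the analysis-window tail
  if (abs(duration_s - nT * hop_s) > 0.5) {
    stop("duration_s inconsistent with the feature matrix")
  }
  fwd <- cnn_forward(m, model)
  scores <- fwd$prepool %*% model$params$cls.W
  if (include_bias) scores <- sweep(scores, 2L, model$params$cls.b, `+`)
  raw <- scores[, 2L]                           # DE[+] vector
  n_sec <- ceiling(duration_s)
  pos <- pmin(length(raw) - 1L, pmax(0L, floor((seq_len(n_sec) - 1L) / stride_s)))
  structure(list(raw = raw, stride_s = stride_s,
                 per_second = raw[pos + 1L],
                 logit_de = fwd$prediction$logits[2L],
                 prediction = fwd$prediction),
            class = "saliency_track")
}

#' Salient administered fraction per neuropsychological test
#'
#' For each annotated test, SAF\[+\] is the fraction of its administered
#' seconds whose DE\[+\] saliency is strictly positive; SAF\[-\] uses the
#' complementary seconds (saliency <= 0). A second with integer index `s`
#' (covering `[s, s+1)`) is attributed to a test when `s` lies inside the
#' test's half-open interval. Zero-length coverage is excluded with a warning.
#'
#' @param track a [compute_saliency()] result (or any list with a
#'   `per_second` vector).
#' @param seg a [segmentation()].
#' @param sign `"+"` (saliency > 0) or `"-"` (saliency <= 0).
#' @return Named numeric vector, one fraction in \[0, 1\] per test.
#' @export
saf <- function(track, seg, sign = c("+", "-")) {
  sign <- match.arg(sign)
  ps <- track$per_second
  n_sec <- length(ps)
  tests <- unique(seg$test_name)
  out <- stats::setNames(numeric(0), character(0))
  for (tn in tests) {
    rows <- seg[seg$test_name == tn, , drop = FALSE]
    secs <- integer(0)
    for (i in seq_len(nrow(rows))) {
      lo <- ceiling(rows$start_s[i])
      hi <- ceiling(rows$end_s[i]) - 1L
      if (hi >= lo) secs <- c(secs, lo:hi)
    }
    secs <- secs[secs >= 0L & secs < n_sec]
    if (length(secs) == 0L) {
      warning("test '", tn, "' covers no whole second; excluded")
      next
    }
    v <- ps[secs + 1L]
    frac <- if (sign == "+") mean(v > 0) else mean(v <= 0)
    out[tn] <- frac
  }
  out
}

#' Aggregate SAF values over true-positive / true-negative recordings
#'
#' SAF\[+\] is averaged over recordings of DE participants that the model
#' classified as DE (true positives); SAF\[-\] over negative-class recordings
#' classified negative (true negatives). False positives and false negatives
#' contribute to neither column. Tests appearing in fewer than `min_n`
#' recordings (on both sides) are routed to a separate low-sample table.
#'
#' @param results list of per-recording lists, each with elements `track`
#'   (a [compute_saliency()] result), `seg` (a [segmentation()]), `truth`
#'   (1 = negative class, 2 = DE) and `predicted` (same coding).
#' @param min_n minimum `max(n+, n-)` for the main table. Default 10.
#' @return List with data frames `main` and `low_n`, columns: `test_name`,
#'   `saf_pos_mean`, `saf_pos_sd`, `saf_neg_mean`, `saf_neg_sd`, `n_pos`,
#'   `n_neg`. Single-recording groups report sd 0.
#' @export
aggregate_saf <- function(results, min_n = 10) {
  is_tp <- vapply(results, function(r) r$truth == 2L && r$predicted == 2L, logical(1))
  is_tn <- vapply(results, function(r) r$truth == 1L && r$predicted == 1L, logical(1))
  if (!any(is_tp) && !any(is_tn)) {
    warning("no true-positive or true-negative recordings; empty SAF table")
  }
  pos_vals <- collect_saf(results[is_tp], "+")
  neg_vals <- collect_saf(results[is_tn], "-")
  tests <- sort(unique(c(names(pos_vals), names(neg_vals))))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  tab <- do.call(rbind, lapply(tests, function(tn) {
    vp <- pos_vals[[tn]]; vn <- neg_vals[[tn]]
    data.frame(test_name = tn,
               saf_pos_mean = if (length(vp)) mean(vp) else NA_real_,
               saf_pos_sd = if (length(vp)) sd0(vp) else NA_real_,
               saf_neg_mean = if (length(vn)) mean(vn) else NA_real_,
               saf_neg_sd = if (length(vn)) sd0(vn) else NA_real_,
               n_pos = length(vp), n_neg = length(vn),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(test_name = character(), saf_pos_mean = numeric(),
                      saf_pos_sd = numeric(), saf_neg_mean = numeric(),
                      saf_neg_sd = numeric(), n_pos = integer(),
                      n_neg = integer())
  }
  low <- pmax(tab$n_pos, tab$n_neg) < min_n
  ord <- order(-replace(tab$saf_pos_mean, is.na(tab$saf_pos_mean), -Inf))
  tab <- tab[ord, , drop = FALSE]
  low <- low[ord]
  rownames(tab) <- NULL
  list(main = tab[!low, , drop = FALSE], low_n = tab[low, , drop = FALSE])
}

# per-test lists of SAF values over a set of recordings
collect_saf <- function(results, sign) {
  vals <- list()
  for (r in results) {
    s <- saf(r$track, r$seg, sign)
    for (tn in names(s)) vals[[tn]] <- c(vals[[tn]], s[[tn]])
  }
  vals
}
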