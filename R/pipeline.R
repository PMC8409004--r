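#' Featurize every recording of a synthetic cohort
#'
#' Renders each recording's audio from its stored seed and extracts the
#' 13-dimensional MFCC sequence, discarding the waveform immediately so
#' memory stays proportional to the feature matrices.
#'
#' @param cohort a [generate_cohort()] result.
#' @param fcfg a [feature_config()].
#' @return Named list of [mfcc()] objects keyed by recording id.
#' @export
cohort_features <- function(cohort, fcfg = feature_config()) {
  ids <- cohort$manifest$recording_id
  out <- vector("list", length(ids))
  names(out) <- ids
  for (rid in ids) {
    w <- recording_waveform(cohort, rid, rate = fcfg$rate)
    out[[rid]] <- extract_mfcc(w, fcfg)
  }
  out
}

#' Binary task labels for a cohort
#'
#' Maps cognitive statuses to the two modeled tasks: `"nc_vs_de"` keeps NC
#' (class 1) and DE (class 2) recordings only; `"de_vs_nde"` codes NC and MCI
#' as the negative class (NDE) and DE as positive.
#'
#' @param labels character vector of statuses (`NC`, `MCI`, `DE`).
#' @param task `"nc_vs_de"` or `"de_vs_nde"`.
#' @return Integer vector (1 = negative, 2 = DE, `NA` = excluded).
#' @export
task_labels <- function(labels, task = c("nc_vs_de", "de_vs_nde")) {
  task <- match.arg(task)
  y <- ifelse(labels == "DE", 2L,
              ifelse(labels == "NC" | task == "de_vs_nde", 1L, NA_integer_))
  as.integer(y)
}

#' Participant-level k-fold cross-validation of a classifier
#'
#' Splits participants into folds, trains one model per fold on the
#' out-of-fold recordings and scores the in-fold recordings. Fold training
#' seeds are derived deterministically from `seed`.
#'
#' @param features named list of [mfcc()] objects.
#' @param labels integer task labels (1/2) aligned with `features`.
#' @param participant_ids participant id per recording.
#' @param model_type `"lstm"` or `"cnn"`.
#' @param k folds. Default 5.
#' @param tc a [train_config()]; its `seed` seeds the splits and fans out to
#'   per-fold initialization/training seeds.
#' @param lstm_cfg,cnn_cfg model configurations.
#' @return List with `predictions` (data frame: recording, fold, truth,
#'   score, predicted), `fold_metrics`, `summary` ([summarize_metrics()]),
#'   and `models` (one trained model per fold).
#' @export
cross_validate <- function(features, labels, participant_ids,
                           model_type = c("lstm", "cnn"), k = 5,
                           tc = train_config(),
                           lstm_cfg = lstm_config(), cnn_cfg = cnn_config()) {
  model_type <- match.arg(model_type)
  stopifnot(length(features) == length(labels),
            length(labels) == length(participant_ids))
  keep <- !is.na(labels)
  features <- features[keep]
  labels <- labels[keep]
  participant_ids <- participant_ids[keep]
  split <- make_splits(unique(participant_ids), k = k, test_fraction = 0,
                       seed = tc$seed)
  preds <- list()
  fold_metrics <- list()
  models <- list()
  for (f in seq_len(k)) {
    in_fold <- participant_ids %in% split$folds[[f]]
    fold_seed <- (tc$seed * 1000L + f) %% .Machine$integer.max
    model <- if (model_type == "lstm") {
      init_lstm_model(lstm_cfg, seed = fold_seed)
    } else {
      init_cnn_model(cnn_cfg, seed = fold_seed)
    }
    ftc <- tc
    ftc$seed <- fold_seed
    fit <- train_model(model, features[!in_fold], labels[!in_fold], ftc)
    models[[f]] <- fit$model
    sc <- vapply(features[in_fold],
                 function(m) predict_recording(fit$model, m)$probs[2L],
                 numeric(1))
    truth <- labels[in_fold]
    preds[[f]] <- data.frame(recording_id = names(features)[in_fold],
                             fold = f, truth = truth, score = sc,
                             predicted = ifelse(sc > 0.5, 2L, 1L),
                             stringsAsFactors = FALSE)
    fold_metrics[[f]] <- compute_metrics(truth, sc)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  list(predictions = predictions, fold_metrics = fold_metrics,
       summary = summarize_metrics(fold_metrics), models = models)
}

#' Pooled cross-validated ROC AUC
#' @param cv a [cross_validate()] result.
#' @return ROC AUC over all out-of-fold predictions pooled together.
#' @export
cv_pooled_auc <- function(cv) {
  roc_auc(cv$predictions$truth, cv$predictions$score)
}
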