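# voxcog

Automated dementia screening from voice recordings of neuropsychological
examinations.

## The problem

Neuropsychological exams of older adults are routinely audio-recorded:
hour-scale mono recordings with two speakers (examiner and participant).
These recordings carry signal about cognitive status in how the participant
speaks — pauses, speaking rate, vocal stability — and in how long each test
takes to administer, but analyzing them has traditionally required manual
transcription. `voxcog` implements a transcription-free pipeline for
clinicians and methods researchers working on audio-based cognitive
screening: raw WAV in, probability of dementia out, plus a temporal map of
*where* in the exam the model found its evidence.

Because the clinical recordings such pipelines are built on are restricted,
the package includes a synthetic exam-cohort generator with the same
statistical structure (repeat visits, class-conditional test durations and
acoustics), so the entire workflow is reproducible from code alone.

## Methods at the core

* **Acoustic front end.** 13-dimensional MFCC vectors at a 10 ms hop:
  25 ms frames (200 samples at 8 kHz), 256-point periodogram, 26 triangular
  Mel filters (mel(f) = 2595·log₁₀(1 + f/700)) on 0–4 kHz, log, orthonormal
  DCT-II; cepstral coefficients c₂…c₁₃ plus the log total frame energy in
  place of c₁.
* **Hierarchical LSTM.** Frames are grouped into 2000-frame segments; a
  low-level LSTM (hidden dim 64) reads 10 concatenated frames per step and
  emits one vector per segment; a high-level LSTM summarizes the segment
  sequence; an MLP + softmax yields P(DE). Handles arbitrarily long input.
* **1-D CNN with global average pooling (GAP).** Seven blocks of two
  kernel-3 convolutions (ReLU each); the first six end in stride-4 max
  pooling, so each surviving position spans 4096 frames (~41 s); GAP +
  linear classifier yield the logits for any input length.
* **Temporal saliency and SAF.** Since GAP and a linear classifier commute,
  applying the classifier position-wise to the pre-GAP features gives a
  DE[+] evidence track whose mean equals the recording logit exactly.
  Expanded to per-second resolution, the *salient administered fraction*
  SAF[+] of a neuropsychological test is the fraction of its administered
  seconds with positive DE[+] saliency (SAF[−] the complement), aggregated
  over true-positive (resp. true-negative) recordings.
* **Evaluation.** 180-day diagnosis-timeline labeling (NC/MCI/DE),
  participant-level 5-fold cross-validation, a full binary metric suite
  (ROC/PR AUC by trapezoid, balanced accuracy, weighted F1, MCC), random
  short-excerpt evaluation, and Welch-t duration comparisons by group.

Both networks are implemented natively (R orchestration over compiled
Rcpp/Armadillo kernels) with backpropagation verified against finite
differences, trained with Adam (lr 1e-4, betas (0.99, 0.999), batch size 4,
inverse-frequency class weights).

## Worked example

```r
library(voxcog)

# a synthetic exam cohort: ~120 recordings, 60 participants, 60-120 s each
cohort <- generate_cohort(cohort_config(n_participants = 60, seed = 101))
table(cohort$manifest$label)
#>  DE MCI  NC
#>  43  36  47

feats <- cohort_features(cohort)          # render audio -> MFCC per recording
y     <- task_labels(cohort$manifest$label, "nc_vs_de")

cv <- cross_validate(feats, y, cohort$manifest$participant_id,
                     "lstm", k = 5, tc = train_config(epochs = 30, seed = 7))
round(cv_pooled_auc(cv), 3)
#> [1] 1
```

`cv_pooled_auc` is the ROC AUC over all out-of-fold predictions: at full
synthetic effect strength the hierarchical LSTM ranks every held-out
dementia recording above every normal-cognition one (the same protocol on a
cohort with all class effects silenced stays at chance — the acceptance
suite checks both). Saliency for one recording of a trained CNN:

```r
fit <- train_model(init_cnn_model(), feats[!is.na(y)], y[!is.na(y)],
                   train_config(epochs = 30, seed = 23))
rid   <- cohort$manifest$recording_id[1]
track <- compute_saliency(fit$model, feats[[rid]],
                          cohort$manifest$duration_s[1])
saf(track, cohort$segmentations[[rid]], "+")   # per-test SAF[+] fractions
```

The numbered scripts under `analysis/` run the full study workflow —
simulation, duration statistics, cross-validated training of both models,
SAF tables, short-excerpt evaluation — writing tables under `results/`.

## Scope

The pipeline's headline clinical numbers in the literature come from
restricted cohort data and are out of scope here; the synthetic cohort
validates the machinery (recovering planted timing/acoustic structure), not
clinical performance. Speech-to-text, speaker diarization and compressed
audio formats are out of scope by design.
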