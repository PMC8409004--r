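---
title: "Methods: automated dementia screening from exam voice recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated dementia screening from exam voice recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxcog)
```

## The problem

Neuropsychological examinations of older adults are routinely audio-recorded.
The recordings are long (tens of minutes to hours), contain two speakers
(examiner and participant), and carry signal about the participant's
cognitive status both in *how* they speak (pauses, speaking rate, vocal
stability) and in *how long* each test takes to administer. `voxcog`
implements an automated screening pipeline that maps a raw mono recording to
a probability of dementia (DE) versus a negative class (normal cognition,
NC, or the non-demented composite NDE = NC + MCI), with no transcription,
diarization or hand-crafted features.

The pipeline has five stages: acoustic front end (MFCCs), one of two
sequence classifiers (hierarchical LSTM or 1-D CNN), temporal saliency
derived from the CNN, salient administered fractions (SAF) per
neuropsychological test, and a cohort-level evaluation harness. Because the
clinical recordings that motivated this design are restricted, the package
ships a synthetic exam-cohort generator with the same statistical structure,
so every stage is exercised end-to-end by code alone.

## Acoustic front end

Audio is ingested as PCM WAV at any rate/channel count, mixed to mono by the
arithmetic channel mean (both speakers share one track, so no channel is
privileged) and resampled to 8 kHz with a polyphase anti-aliased resampler.
Features are Mel-frequency cepstral coefficients:

* frames of 25 ms (200 samples) every 10 ms (80 samples); trailing samples
  that do not fill a window are dropped, so a signal of `n` samples yields
  `1 + floor((n - 200)/80)` frames;
* a periodogram per frame: zero-padding 200 to 256 points, 256-point DFT,
  one-sided power `|X[k]|^2 / 200` for `k = 0..128`;
* 26 triangular filters with peaks evenly spaced on the Mel axis
  (`mel(f) = 2595 log10(1 + f/700)`) between 0 and 4000 Hz, each normalized
  to peak 1 on the sampled bin grid;
* natural log of the filterbank energies, floored at `eps = 1e-10` so silence
  is well-defined, then an orthonormal DCT-II;
* cepstral coefficients 2-13 are kept (1-based); coefficient 1 is discarded
  and replaced by the natural-log total energy of the raw frame, giving the
  final 13-dimensional vector `[log energy, c2..c13]`.

Numerical choices that were genuinely open, and how they were pinned:

* **Analysis taper.** The default is rectangular — the most literal reading
  of a "periodogram estimate" — with Hamming selectable in
  `feature_config()`. Tests pin the default.
* **Energy substitution.** "Total energy" is log-compressed
  (`ln(sum(frame^2))`) so it lives on the same scale as the log-cepstral
  coefficients; the log base is natural throughout.
* **Filter normalization.** Peak-1 normalization is applied on the DFT bin
  grid rather than in the continuous frequency domain, so the stated
  "every filter peaks at 1" holds for the matrix actually used.
* **No pre-emphasis, liftering, or cepstral mean normalization** — the
  front end is deliberately minimal.

Scaling the waveform by `a > 0` shifts the energy column by `2 ln a` and
leaves the cepstral columns unchanged; this covariance is property-tested.

## Hierarchical LSTM

An hour-scale recording yields ~10^5 MFCC frames — far beyond what a single
recurrence can digest. The hierarchical LSTM therefore:

1. groups every 2000 consecutive frames into non-overlapping segments, the
   last segment zero-padded to a multiple of 10 frames;
2. feeds each segment to a low-level LSTM reading 10 concatenated frames
   (130 dims) per step — read as non-overlapping grouping, not subsampling —
   and keeps the final hidden state (64 dims) as the segment vector;
3. runs a high-level LSTM (also 64-dim, separate weights, zero initial
   states at both levels) over the segment vectors and keeps its final
   hidden state as the recording summary;
4. maps the summary through an MLP (64-dim hidden layer, ReLU — the
   nonlinearity is unnamed in the source design, ReLU is the conventional
   choice) to two logits and a softmax.

## 1-D CNN with global average pooling

The convolutional model stacks 7 blocks of two kernel-3, stride-1,
padding-1 convolutions over the feature time axis (ReLU after each
convolution; the per-block "one nonlinearity" is read as per-convolution
ReLU, and the block order conv-ReLU-conv-ReLU-pool is fixed by config). The
first 6 blocks end in max pooling with kernel 4 = stride 4, so each position
surviving to the top spans `4^6 = 4096` frames (~41 s at the 10 ms hop);
`n_pool_blocks = 7` is selectable, which widens the span to ~164 s (about
2.5 min per position). The default is 6: it is the variant consistent with
"max pooling in the first six blocks" and with the pooling law
`L = max(1, floor(T/4096))` that the tests enforce; the saliency stride is
always derived from the configuration, never hard-coded. Channel widths are
unprinted in the source design; the default `[16, 32, 32, 64, 64, 128, 128]`
keeps desk-scale training fast and is configurable. Global average pooling
collapses the `L x 128` map to one vector, and a linear classifier produces
two logits. Inputs shorter than one position span are right-zero-padded;
the average runs over all surviving positions.

Both models are implemented natively (vectorized R orchestration over
compiled kernels for the LSTM time loop, convolutions and pooling) with
full backpropagation verified against central finite differences at 1e-6
perturbation, and trained with Adam (learning rate 1e-4, betas
(0.99, 0.999)) on minibatches of 4 variable-length recordings. The LSTM
freezes a sequence's state once past its true length, so batched and
per-sequence processing agree exactly. Cross-entropy is weighted by inverse
class frequency (DE is the minority class in the cohorts this design
targets). Ties at probability 0.5 resolve to the negative class. A single
training seed fans out to initialization and shuffling, making runs
bit-reproducible.

## Saliency and salient administered fractions

Because global average pooling and the linear classifier commute, applying
the classifier position-wise to the pre-pool feature map yields a temporal
evidence track whose mean *is* the recording-level logit (checked to 1e-5).
The DE row of that track is the DE[+] saliency. The classifier bias is
included per position so the identity is exact; a bias-free variant is a
one-flag change. The track is expanded to one value per second by span
membership — each second belongs to the position whose temporal span
contains it, clamped at the edges — which equals nearest-neighbour
interpolation on position centres for uniform spans.

For each annotated neuropsychological test, SAF[+] is the fraction of its
administered seconds with strictly positive DE[+] saliency; SAF[-] uses the
complement (saliency <= 0), so SAF[+] + SAF[-] = 1 per (recording, test). A
second with integer index `s` (covering `[s, s+1)`) is attributed to a test
when `s` lies in the test's half-open interval; a second straddling two
tests therefore goes to the later one, a convention the source design left
unstated. SAF[+] is aggregated over true-positive recordings only and
SAF[-] over true negatives; false calls contribute to neither. Groups of
one report sd 0 alongside their n. Tests seen in fewer recordings than a
configurable minimum (default 10) are routed to a separate low-sample
table.

## Cohort labeling, splits and metrics

A recording is labeled from the participant's diagnosis timeline by the
180-day rule: among diagnoses on/before the recording or within 180 days
after, the closest in absolute days wins; an equidistant before/after tie
prefers the earlier diagnosis (anchoring on status at testing time — a
choice the rule text leaves open). If the only diagnoses are more than 180
days after, the closest is used only when it is NC; otherwise the recording
is UNLABELED and excluded.

Cross-validation splits are drawn at the participant level (all of a
participant's recordings stay together) into a held-out test fraction
(default 20%, configurable — the source design kept "a portion" aside
without printing it) and 5 folds balanced in participant count within one.

The metric suite computes accuracy, balanced accuracy (= mean of
sensitivity and specificity, an identity the tests enforce), sensitivity,
specificity, precision, F1, support-weighted F1, Matthews correlation, and
ROC/PR AUCs by trapezoidal integration over the exact step curves (no
smoothing). Fold summaries use the sample (n-1) sd. Duration comparisons
use Welch's t-test by default (the design says only "pairwise t-test";
Student's is selectable) with the conventional star codes.

## The synthetic cohort: what it emulates and what it does not

The generator reproduces the statistical skeleton the analysis relies on:

* **Study structure** — 60 participants with 1-3 recordings each (~120
  recordings), recording-level class mix 0.4/0.3/0.3 over NC/MCI/DE.
  Per-recording statuses are drawn from the mix and sorted within
  participant, so trajectories only progress (NC at an early visit, MCI or
  DE later) while the marginal mix matches the configuration exactly.
  Timelines place a diagnosis on each recording date, so the 180-day rule
  recovers every intended label by construction.
* **Class-conditional timing** — per-test durations are truncated normals
  (floor 5 s before scaling) with the reference battery's per-class means
  and sds (27 tests, e.g. Boston Naming Test NC 405.9 +/- 176.8 s vs DE
  611.1 +/- 260.2 s), scaled by `duration_scale`. The desk default 0.016
  yields ~60-120 s recordings; scale 1 reproduces hour-scale exams
  (~73 min on average) but is not exercised in tests.
* **Class-conditional acoustics** — alternating examiner/participant
  "utterances" rendered as harmonic tone complexes (speaker-specific f0
  bands), amplitude-modulated at a syllabic rate, separated by pauses.
  At full effect, DE speech has a +0.20 higher pause fraction, a 30% slower
  syllable rate and 4x the f0 jitter of NC speech; MCI sits between; the
  examiner always speaks NC-like. All effects scale linearly with
  `effect_scale`, and at 0 every class is acoustically identically
  distributed. The duration and acoustic pathways have independent knobs
  (`duration_effect`, `effect_scale`) so either can be silenced alone; the
  "null cohort" used to check chance-level behaviour silences both.

It deliberately does **not** emulate phonetic content, speaker overlap,
channel/recording-equipment variation, or examiner behaviour effects.
Passing tests therefore demonstrate that the pipeline recovers class
structure planted in timing and low-level acoustics — not that it detects
dementia in real clinical audio, which requires the restricted recordings.

## Problem sizes and experiment protocol

Desk-scale experiment sizes were chosen so the full workflow runs on a
single CPU in minutes: ~120 recordings of 60-120 s at 8 kHz (6,000-12,000
MFCC frames each), 5-fold participant-level CV, 30 training epochs. With
strong-effect acoustics this recovers pooled CV ROC AUC >= 0.90 for the
hierarchical LSTM (the CNN trails it at this cohort size), and the
all-effects-silenced null cohort stays at chance (AUC within [0.35, 0.65]);
both checks run in the acceptance suite, which reports pooled
(out-of-fold) AUC as its single CV-AUC definition. The short-excerpt
analysis uses 15/30/60 s windows in place of the 5/10/15-minute windows
that apply to hour-scale exams.

At desk scale a recording spans only one or two saliency positions, so
per-recording SAF values are near-binary (a correctly classified DE
recording tends to SAF[+] = 1 across its tests); the statistic's intended
per-test contrast emerges on hour-scale recordings with dozens of
positions. Tests whose scaled duration covers no whole second are excluded
from SAF with a warning.

## Known limitations

* The two printed desk-scale checks aside, headline clinical numbers from
  the motivating study are not reproducible here: they require restricted
  data, and the synthetic cohort makes no claim of acoustic realism.
* The LSTM processes zero-padded tail steps within a segment's final
  10-frame group as genuine input; with 13-dim features this affects at
  most 9 of 2000 frames per segment.
* PR AUC uses trapezoidal integration, which is mildly optimistic versus
  step-wise interpolation for very small test sets.
* `read_wav` supports PCM 8/16-bit integer and 32-bit float WAV only.
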