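#' Reference neuropsychological test battery with per-class duration priors
#'
#' Mean and standard deviation (seconds) of the time spent administering each
#' neuropsychological test, by cognitive group (NC = normal cognition,
#' MCI = mild cognitive impairment, DE = dementia). These priors drive the
#' synthetic cohort's class-conditional test-duration structure: e.g. the
#' Boston Naming Test averages 405.9 +/- 176.8 s for NC participants but
#' 611.1 +/- 260.2 s for DE participants, while tests such as Verbal fluency
#' show essentially no group difference.
#'
#' @return Data frame with `test_name` and `{nc,mci,de}_{mean,sd}` columns,
#'   all in seconds.
#' @export
test_battery <- function() {
  tab <- rbind(
    c("Demographics",                          244.4, 151.0, 178.7, 106.4, 295.5, 163.2),
    c("Logical memory immediate recall",       135.0,  28.6, 116.9,  19.5, 128.9,  38.5),
    c("Visual reproductions immediate recall", 219.3,  79.2, 190.8,  37.9, 236.1,  67.9),
    c("Verbal paired associates learning",     367.6,  80.4, 366.4,  65.3, 414.3, 155.1),
    c("Digit span forward",                    115.9,  31.4, 100.1,  32.3, 107.5,  36.7),
    c("Digit span backward",                   109.0,  42.5, 128.2,  44.7, 132.6,  52.6),
    c("Logical memory delayed recall",          86.3,  37.8,  57.1,  20.2,  54.0,  25.3),
    c("Logical memory multiple choice",         89.4,  18.3, 103.8,  31.2, 138.9,  62.3),
    c("Visual reproductions delayed recall",   140.6,  73.2, 114.8,  28.3,  79.1,  48.2),
    c("Visual reproductions multiple choice",   63.5,  26.5,  60.9,  27.8,  77.5,  37.1),
    c("Verbal paired associates recall",        66.2,  23.5,  85.6,  43.7,  90.3,  48.7),
    c("Verbal paired associates recognition",   75.8,  21.6,  90.0,  26.4, 126.0,  52.2),
    c("Similarities",                          227.8,  89.6, 217.3,  79.5, 228.0, 120.4),
    c("Command clock",                          80.9,  31.2,  83.3,  29.1, 133.0,  82.2),
    c("Verbal fluency",                        325.5,  39.0, 330.0,  29.2, 336.1,  65.4),
    c("Boston Naming Test",                    405.9, 176.8, 321.2,  93.8, 611.1, 260.2),
    c("Copy clock",                             70.1,  33.5,  54.7,  14.0,  90.9,  44.4),
    c("Trails A",                              115.4,  58.3, 105.3,  23.7, 199.0, 107.1),
    c("Trails B",                              219.2, 107.6, 241.0, 117.5, 431.2, 278.0),
    c("WRAT-3 reading",                        119.7,  36.8, 115.1,  52.3, 142.8,  70.4),
    c("Hooper visual organization test",       398.5, 182.1, 284.1,  90.8, 424.6, 187.4),
    c("Block design (WAIS)",                   357.3, 213.6, 389.7, 145.0, 487.3, 214.3),
    c("Finger tapping",                        294.4, 106.9, 323.8,  87.6, 289.0, 130.6),
    c("Information (WAIS-R)",                  392.7, 181.2, 335.8, 156.9, 372.7, 153.6),
    c("Cookie theft",                          198.9,  75.3, 244.6, 101.7, 186.9, 147.0),
    c("Clock drawing number placement",         47.6,  40.6,  51.8,  20.5,  81.6,  71.5),
    c("Clock drawing time setting",             44.0,  26.9,  37.9,   7.6,  75.3,  59.3)
  )
  df <- data.frame(test_name = tab[, 1], stringsAsFactors = FALSE)
  num <- apply(tab[, -1], 2L, as.numeric)
  colnames(num) <- c("nc_mean", "nc_sd", "mci_mean", "mci_sd", "de_mean", "de_sd")
  cbind(df, num)
}

#' Acoustic effect configuration for synthetic exam audio
#'
#' Synthetic exams contain two alternating "speakers" (examiner and
#' participant) rendered as amplitude-modulated harmonic tone complexes with
#' interleaved pauses over a low noise floor. Class-conditional effects act on
#' the participant's speech only and scale linearly with `effect_scale`:
#' at 0 every class is acoustically identically distributed; at 1 ("strong")
#' DE speech has a markedly higher pause fraction, a slower syllabic rate and
#' less stable fundamental frequency than NC speech.
#'
#' @param effect_scale numeric in \[0, 1\] (0 = no class signal, 1 = strong),
#'   or one of `"zero"`, `"weak"` (0.5), `"strong"` (1).
#' @param base_pause_fraction expected fraction of speech time replaced by
#'   pauses for NC speakers. Default 0.25.
#' @param pause_shift additive pause-fraction shift at full effect,
#'   `c(MCI, DE)`. Default `c(0.08, 0.20)`.
#' @param base_syllable_hz syllabic amplitude-modulation rate for NC speech.
#'   Default 4 Hz.
#' @param rate_slowdown proportional syllable-rate reduction at full effect,
#'   `c(MCI, DE)`. Default `c(0.10, 0.30)`.
#' @param base_jitter relative per-syllable f0 jitter for NC speech.
#'   Default 0.02.
#' @param jitter_gain multiplicative f0-jitter increase at full effect,
#'   `c(MCI, DE)`. Default `c(1, 3)`.
#' @param examiner_f0 examiner f0 band in Hz. Default `c(100, 140)`.
#' @param participant_f0 participant f0 band in Hz. Default `c(180, 240)`.
#' @param noise_level additive white-noise amplitude. Default 0.005.
#' @return An `acoustics_config` list.
#' @export
acoustics_config <- function(effect_scale = "strong",
                             base_pause_fraction = 0.25,
                             pause_shift = c(0.08, 0.20),
                             base_syllable_hz = 4,
                             rate_slowdown = c(0.10, 0.30),
                             base_jitter = 0.02,
                             jitter_gain = c(1, 3),
                             examiner_f0 = c(100, 140),
                             participant_f0 = c(180, 240),
                             noise_level = 0.005) {
  if (is.character(effect_scale)) {
    effect_scale <- switch(match.arg(effect_scale, c("zero", "weak", "strong")),
                           zero = 0, weak = 0.5, strong = 1)
  }
  if (effect_scale < 0 || effect_scale > 1) stop("effect_scale must be in [0, 1]")
  structure(list(effect_scale = effect_scale,
                 base_pause_fraction = base_pause_fraction,
                 pause_shift = pause_shift,
                 base_syllable_hz = base_syllable_hz,
                 rate_slowdown = rate_slowdown,
                 base_jitter = base_jitter,
                 jitter_gain = jitter_gain,
                 examiner_f0 = examiner_f0,
                 participant_f0 = participant_f0,
                 noise_level = noise_level),
            class = "acoustics_config")
}

class_acoustics <- function(label, acfg) {
  e <- acfg$effect_scale
  i <- match(label, c("NC", "MCI", "DE"))
  shift <- c(0, acfg$pause_shift)[i] * e
  slow <- c(0, acfg$rate_slowdown)[i] * e
  jit <- 1 + (c(0, acfg$jitter_gain)[i]) * e
  list(pause_fraction = acfg$base_pause_fraction + shift,
       syllable_hz = acfg$base_syllable_hz * (1 - slow),
       jitter = acfg$base_jitter * jit)
}

#' Synthetic cohort configuration
#'
#' @param n_participants number of participants. Default 60.
#' @param recordings_per_participant probability weights for 1, 2, 3
#'   recordings per participant. Default `c(0.3, 0.4, 0.3)` (two per
#'   participant on average, so 60 participants yield about 120 recordings).
#' @param class_mix recording-level probabilities of NC, MCI, DE. Each
#'   recording's status is drawn from this mix and statuses are sorted
#'   non-decreasingly within participant, so repeat recordings show natural
#'   stage progression (NC at the first visit, MCI or DE later) while the
#'   marginal recording-level mix matches `class_mix` exactly in
#'   distribution. Default `c(0.4, 0.3, 0.3)`.
#' @param duration_scale fraction of realistic exam length; 1 reproduces the
#'   reference battery's hour-scale exams, the desk default 0.016 yields
#'   roughly 60-120 s recordings. Must be in (0, 1].
#' @param duration_effect scales the class-conditional *duration* differences
#'   (0 = every class uses the NC duration priors, 1 = full group
#'   differences); independent of the acoustic effect scale so the two
#'   pathways can be ablated separately. Default 1.
#' @param battery test battery data frame in the format of [test_battery()].
#'   Defaults to the full reference battery.
#' @param acoustics an [acoustics_config()].
#' @param gap_s un-annotated silent gap between consecutive tests (seconds,
#'   not scaled). Default 0.2.
#' @param min_test_s truncation floor for a single test's duration *before*
#'   scaling, i.e. the floor is `min_test_s * duration_scale`. Default 5.
#' @param seed integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 60,
                          recordings_per_participant = c(0.3, 0.4, 0.3),
                          class_mix = c(NC = 0.4, MCI = 0.3, DE = 0.3),
                          duration_scale = 0.016,
                          duration_effect = 1,
                          battery = test_battery(),
                          acoustics = acoustics_config("strong"),
                          gap_s = 0.2,
                          min_test_s = 5,
                          seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (duration_scale <= 0 || duration_scale > 1) {
    stop("duration_scale must be in (0, 1]")
  }
  if (nrow(battery) == 0L) stop("battery must contain at least one test")
  if (any(battery$nc_mean <= 0 | battery$mci_mean <= 0 | battery$de_mean <= 0)) {
    stop("all battery duration means must be positive")
  }
  structure(list(n_participants = as.integer(n_participants),
                 recordings_per_participant = recordings_per_participant,
                 class_mix = class_mix,
                 duration_scale = duration_scale,
                 duration_effect = duration_effect,
                 battery = battery,
                 acoustics = acoustics,
                 gap_s = gap_s,
                 min_test_s = min_test_s,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Truncated-normal draw by rejection (floor only).
rtnorm_floor <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:100) {
    bad <- x < floor
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, floor)
}

# Class-conditional scaled duration for each battery test.
draw_test_durations <- function(label, cfg) {
  b <- cfg$battery
  de <- cfg$duration_effect
  i <- match(label, c("NC", "MCI", "DE"))
  mu_cls <- cbind(b$nc_mean, b$mci_mean, b$de_mean)[, i]
  sd_cls <- cbind(b$nc_sd, b$mci_sd, b$de_sd)[, i]
  mu <- b$nc_mean + de * (mu_cls - b$nc_mean)
  sdv <- b$nc_sd + de * (sd_cls - b$nc_sd)
  s <- cfg$duration_scale
  rtnorm_floor(nrow(b), mu * s, sdv * s, floor = cfg$min_test_s * s)
}

#' Generate a synthetic exam cohort
#'
#' Produces, deterministically under `cfg$seed`: per-participant status
#' trajectories (with occasional stage progression across repeat recordings),
#' diagnosis timelines constructed so the 180-day labeling rule reproduces
#' every intended label, per-recording test segmentations with class-
#' conditional durations, and per-recording audio-synthesis seeds. Audio
#' itself is rendered lazily by [recording_waveform()] (or written to disk
#' when `out_dir` is given) so hour-scale cohorts need not be held in memory.
#'
#' @param cfg a [cohort_config()].
#' @param out_dir optional directory; when given, WAV files, segmentation
#'   TSVs, a timelines CSV and a manifest CSV are written there.
#' @return A `cohort`: list with `manifest` (data frame incl. `label` and
#'   `audio_seed`), `segmentations` (named list), `timelines` (named list)
#'   and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  statuses <- c("NC", "MCI", "DE")
  n_rec_options <- seq_along(cfg$recordings_per_participant)
  rows <- list()
  segmentations <- list()
  timelines <- list()
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%03d", p)
    n_rec <- sample(n_rec_options, 1L, prob = cfg$recordings_per_participant)
    # statuses drawn per recording, sorted so trajectories only progress
    traj <- sort(sample(1:3, n_rec, replace = TRUE, prob = cfg$class_mix))
    first_date <- as.Date("2010-01-01") + sample.int(2000L, 1L)
    tl_rows <- list()
    for (r in seq_len(n_rec)) {
      label <- statuses[traj[r]]
      rec_date <- first_date + (r - 1L) * 365L
      rid <- sprintf("%s-R%d", pid, r)
      dur <- draw_test_durations(label, cfg)
      starts <- cumsum(c(0, utils::head(dur, -1L) + cfg$gap_s))
      seg <- segmentation(data.frame(test_name = cfg$battery$test_name,
                                     start_s = starts,
                                     end_s = starts + dur))
      total_s <- max(seg$end_s) + cfg$gap_s
      segmentations[[rid]] <- seg
      tl_rows[[r]] <- data.frame(diagnosis_date = rec_date, status = label,
                                 stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = rid, participant_id = pid,
        recording_date = rec_date,
        audio_path = paste0(rid, ".wav"),
        duration_s = total_s, label = label,
        audio_seed = sample.int(.Machine$integer.max, 1L),
        stringsAsFactors = FALSE)
    }
    tl <- do.call(rbind, tl_rows)
    timelines[[pid]] <- tl[order(tl$diagnosis_date), , drop = FALSE]
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  cohort <- structure(list(manifest = manifest, segmentations = segmentations,
                           timelines = timelines, config = cfg),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Render (or re-render) the audio of one cohort recording
#'
#' Deterministic given the recording's stored `audio_seed`: the same cohort
#' recording always synthesizes to the identical waveform, whether rendered
#' in memory or written to disk.
#'
#' @param cohort a [generate_cohort()] result.
#' @param recording_id id from the cohort manifest.
#' @param rate sampling rate in Hz. Default 8000.
#' @return A [waveform()].
#' @export
recording_waveform <- function(cohort, recording_id, rate = 8000) {
  m <- cohort$manifest
  i <- match(recording_id, m$recording_id)
  if (is.na(i)) stop("unknown recording_id: ", recording_id)
  synthesize_exam_audio(m$label[i], cohort$segmentations[[recording_id]],
                        cohort$config$acoustics, rate = rate,
                        seed = m$audio_seed[i],
                        total_s = m$duration_s[i])
}

#' Synthesize two-speaker exam-like audio for one recording
#'
#' Within each annotated test interval, examiner and participant "utterances"
#' alternate: harmonic tone complexes (3 harmonics) in speaker-specific f0
#' bands, amplitude-modulated at a syllabic rate, separated by pauses. The
#' participant's pause fraction, syllable rate and f0 jitter carry the
#' class-conditional effects of the [acoustics_config()]; the examiner always
#' speaks with NC-like acoustics. Low-level white noise covers the full
#' recording; the waveform is clipped to \[-1, 1\].
#'
#' @param label cognitive status of the participant (`NC`, `MCI`, `DE`).
#' @param seg a [segmentation()].
#' @param acfg an [acoustics_config()].
#' @param rate sampling rate in Hz. Default 8000.
#' @param seed integer RNG seed (determinism contract).
#' @param total_s total duration; defaults to the last interval end.
#' @return A [waveform()].
#' @export
synthesize_exam_audio <- function(label, seg, acfg = acoustics_config(),
                                  rate = 8000, seed = 1L, total_s = NULL) {
  set.seed(seed)
  if (is.null(total_s)) total_s <- max(seg$end_s)
  n <- ceiling(total_s * rate)
  x <- stats::rnorm(n, 0, acfg$noise_level)
  part <- class_acoustics(label, acfg)
  exam <- class_acoustics("NC", acfg)
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$start_s[i]; t1 <- seg$end_s[i]
    speaker_is_examiner <- stats::runif(1) < 0.5
    t <- t0
    while (t < t1) {
      sp <- if (speaker_is_examiner) exam else part
      band <- if (speaker_is_examiner) acfg$examiner_f0 else acfg$participant_f0
      ulen <- min(stats::runif(1, 0.6, 1.8), t1 - t)
      if (ulen > 0.05) {
        f0 <- stats::runif(1, band[1], band[2]) *
          (1 + stats::rnorm(1, 0, sp$jitter))
        tt <- seq(0, ulen, by = 1 / rate)[-1]
        # slow f0 wander whose scale tracks the class jitter
        f_inst <- f0 * (1 + sp$jitter * sin(2 * pi * stats::runif(1, 0.5, 2) * tt))
        phase <- 2 * pi * cumsum(f_inst) / rate
        sig <- 0.5 * sin(phase) + 0.25 * sin(2 * phase) + 0.12 * sin(3 * phase)
        env <- 0.5 * (1 - cos(2 * pi * sp$syllable_hz * tt))
        sig <- 0.45 * sig * env
        i0 <- floor(t * rate) + 1L
        idx <- i0:min(i0 + length(sig) - 1L, n)
        x[idx] <- x[idx] + sig[seq_along(idx)]
      }
      pf <- min(sp$pause_fraction, 0.95)
      pause <- ulen * pf / (1 - pf) * stats::runif(1, 0.6, 1.4)
      t <- t + ulen + pause
      speaker_is_examiner <- !speaker_is_examiner
    }
  }
  waveform(pmin(1, pmax(-1, x)), rate)
}

#' Write a cohort to disk (WAVs, segmentation TSVs, timelines, manifest)
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    rid <- m$recording_id[i]
    write_wav(recording_waveform(cohort, rid),
              file.path(out_dir, m$audio_path[i]))
    write_segmentation(cohort$segmentations[[rid]],
                       file.path(out_dir, paste0(rid, ".tsv")))
  }
  tls <- lapply(cohort$timelines, identity)
  write_timelines(tls, file.path(out_dir, "timelines.csv"))
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}

#' Fraction of low-energy (pause) frames in a waveform
#'
#' A simple energy-threshold silence detector used to validate the synthetic
#' generator's class-conditional pause structure: frames whose RMS falls
#' below `thresh` count as pauses.
#'
#' @param w a [waveform()].
#' @param frame_s frame length in seconds. Default 0.025.
#' @param thresh RMS threshold. Default 0.02.
#' @return Pause fraction in \[0, 1\].
#' @export
measure_pause_fraction <- function(w, frame_s = 0.025, thresh = 0.02) {
  n <- floor(frame_s * w$rate)
  k <- length(w$samples) %/% n
  m <- matrix(w$samples[seq_len(k * n)], nrow = n)
  rms <- sqrt(colMeans(m^2))
  mean(rms < thresh)
}
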