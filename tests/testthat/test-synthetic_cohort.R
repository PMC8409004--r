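test_that("cohort generation is deterministic under seed", {
  cfg <- cohort_config(n_participants = 8, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$segmentations, b$segmentations)
  expect_identical(a$timelines, b$timelines)
  # rendered audio is reproducible too
  rid <- a$manifest$recording_id[1]
  expect_identical(recording_waveform(a, rid)$samples,
                   recording_waveform(b, rid)$samples)
})

test_that("written cohorts round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_participants = 3, seed = 4,
                       battery = test_battery()[1:4, ])
  coh <- generate_cohort(cfg, out_dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), nrow(coh$manifest))
  rid <- man$recording_id[1]
  seg <- read_segmentation(file.path(dir, paste0(rid, ".tsv")))
  expect_equal(seg$test_name, coh$segmentations[[rid]]$test_name)
  tls <- read_timelines(file.path(dir, "timelines.csv"))
  expect_setequal(names(tls), names(coh$timelines))
  w <- read_wav(file.path(dir, paste0(rid, ".wav")), target_rate = 8000)
  expect_equal(duration_s(w), man$duration_s[man$recording_id == rid],
               tolerance = 1e-3)
})

test_that("recording-level class mix stays within binomial 99% bounds", {
  cfg <- cohort_config(n_participants = 50, seed = 33)
  coh <- generate_cohort(cfg)
  n <- nrow(coh$manifest)
  for (cls in c("NC", "MCI", "DE")) {
    p <- cfg$class_mix[[cls]]
    k <- sum(coh$manifest$label == cls)
    lo <- qbinom(0.005, n, p); hi <- qbinom(0.995, n, p)
    expect_true(k >= lo && k <= hi,
                label = sprintf("%s count %d in [%d, %d]", cls, k, lo, hi))
  }
})

test_that("test durations at scale 1 recover the battery priors within 3 SE", {
  cfg <- cohort_config(n_participants = 60, duration_scale = 1, seed = 8,
                       battery = test_battery()[c(1, 16, 19), ])
  coh <- generate_cohort(cfg)   # durations only; audio never rendered
  b <- cfg$battery
  for (cls in c("NC", "DE")) {
    ids <- coh$manifest$recording_id[coh$manifest$label == cls]
    if (length(ids) < 20) next
    for (i in seq_len(nrow(b))) {
      durs <- vapply(ids, function(rid) {
        s <- coh$segmentations[[rid]]
        s$end_s[i] - s$start_s[i]
      }, numeric(1))
      mu <- if (cls == "NC") b$nc_mean[i] else b$de_mean[i]
      sdv <- if (cls == "NC") b$nc_sd[i] else b$de_sd[i]
      se <- sdv / sqrt(length(durs))
      expect_lt(abs(mean(durs) - mu), 3 * se + 1e-9)
    }
  }
})

test_that("the labeling rule reproduces every intended label", {
  coh <- generate_cohort(cohort_config(n_participants = 25, seed = 13))
  m <- coh$manifest
  relabeled <- vapply(seq_len(nrow(m)), function(i) {
    assign_label(m$recording_date[i], coh$timelines[[m$participant_id[i]]])
  }, character(1))
  expect_equal(relabeled, m$label)
})

test_that("statuses only progress within a participant", {
  coh <- generate_cohort(cohort_config(n_participants = 40, seed = 3))
  rank <- c(NC = 1, MCI = 2, DE = 3)
  for (pid in names(coh$timelines)) {
    expect_false(is.unsorted(rank[coh$timelines[[pid]]$status]))
  }
})

test_that("synthetic audio respects amplitude bounds and segment layout", {
  seg <- seg_fixture(test_name = c("A", "B"), start_s = c(0, 6),
                     end_s = c(5, 12))
  w <- synthesize_exam_audio("DE", seg, acoustics_config("strong"), seed = 2,
                             total_s = 12.5)
  expect_true(all(abs(w$samples) <= 1))
  expect_equal(duration_s(w), 12.5, tolerance = 1e-3)
  # determinism
  w2 <- synthesize_exam_audio("DE", seg, acoustics_config("strong"), seed = 2,
                              total_s = 12.5)
  expect_identical(w$samples, w2$samples)
})

test_that("DE audio pauses more than NC audio at strong effect", {
  seg <- seg_fixture(test_name = "T", start_s = 0, end_s = 20)
  acfg <- acoustics_config("strong")
  pf <- function(label, seed) {
    measure_pause_fraction(synthesize_exam_audio(label, seg, acfg, seed = seed))
  }
  de <- vapply(1:12, function(s) pf("DE", s), numeric(1))
  nc <- vapply(1:12, function(s) pf("NC", s + 500), numeric(1))
  expect_gt(mean(de), mean(nc) + 0.05)
})

test_that("at zero effect the pause-fraction distributions coincide", {
  seg <- seg_fixture(test_name = "T", start_s = 0, end_s = 15)
  acfg <- acoustics_config("zero")
  de <- vapply(1:60, function(s)
    measure_pause_fraction(synthesize_exam_audio("DE", seg, acfg, seed = s)),
    numeric(1))
  nc <- vapply(1:60, function(s)
    measure_pause_fraction(synthesize_exam_audio("NC", seg, acfg, seed = s + 900)),
    numeric(1))
  ks <- suppressWarnings(ks.test(de, nc))
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(battery = test_battery()[0, ]), "at least one")
  expect_error(cohort_config(class_mix = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(cohort_config(duration_scale = 0), "duration_scale")
  expect_error(acoustics_config(effect_scale = 2), "effect_scale")
})
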