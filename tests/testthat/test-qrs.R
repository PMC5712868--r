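# QRS detection and per-beat features.

test_that("degenerate records yield no beats", {
  expect_length(detect_qrs(ecg_record(numeric(), fs = 200))$beat_samples, 0L)
  expect_length(detect_qrs(ecg_record(numeric(300), fs = 200))$beat_samples, 0L)
  expect_length(detect_qrs(ecg_record(numeric(2000), fs = 200))$beat_samples, 0L)
})

test_that("clean 60-bpm sinus beats are found within 50 ms of truth", {
  s <- synth_record(synth_config(rhythm_plan = plan_segment("SINUS", 60),
                                 sinus_rate_bpm = 60, rr_jitter_sd = 0,
                                 seed = 4))
  b <- detect_qrs(s$record)
  truth <- s$annotation$beats$sample
  expect_equal(length(b$beat_samples), length(truth))
  expect_lt(max(abs(b$beat_samples - truth)) / 200, 0.050)
})

test_that("detection survives 20 dB white noise at over 99% Se and +P", {
  s <- synth_record(synth_config(rhythm_plan = plan_segment("SINUS", 60),
                                 sinus_rate_bpm = 60, noise_snr_db = 20,
                                 seed = 4))
  b <- detect_qrs(s$record)
  m <- match_beats(s$annotation, beats_as_annotation(b), "N", fs = 200,
                   tolerance_s = 0.15)
  st <- beat_stats(m)
  expect_gte(st[["se"]], 99)
  expect_gte(st[["pp"]], 99)
})

test_that("beat spacing respects the refractory period and ordering", {
  for (seed in 1:3) {
    s <- synth_record(synth_config(
      rhythm_plan = plan_segment("AF", 120), seed = seed))
    b <- detect_qrs(s$record)
    expect_true(all(diff(b$beat_samples) > 0))
    expect_true(all(diff(b$beat_samples) >= 0.2 * 200))
  }
})

test_that("detection is invariant to positive amplitude scaling", {
  s <- synth_record(synth_config(rhythm_plan = plan_segment("SINUS", 30),
                                 seed = 6))
  b1 <- detect_qrs(s$record)
  scaled <- ecg_record(s$record$samples * 7.3, fs = 200)
  b2 <- detect_qrs(scaled)
  expect_identical(b1$beat_samples, b2$beat_samples)
})

test_that("a time shift moves beats but not RR intervals", {
  s <- synth_record(synth_config(rhythm_plan = plan_segment("SINUS", 30),
                                 seed = 6))
  b1 <- detect_qrs(s$record)
  k <- 400
  shifted <- ecg_record(c(numeric(k), s$record$samples), fs = 200)
  b2 <- detect_qrs(shifted)
  # every original beat reappears shifted by exactly k; the padded onset may
  # add spurious detections before the first true beat, nowhere else
  expect_true(all((b1$beat_samples + k) %in% b2$beat_samples))
  idx <- match(b1$beat_samples + k, b2$beat_samples)
  expect_equal(diff(idx), rep(1L, length(idx) - 1L))  # no insertions inside
  expect_equal(diff(b1$beat_samples), diff(b2$beat_samples[idx]))
})

test_that("rr_intervals follows its definition", {
  expect_equal(rr_intervals(beat_series(c(200, 400, 600), fs = 200)),
               c(1, 1))
  expect_equal(rr_intervals(beat_series(c(200, 300, 600), fs = 200)),
               c(0.5, 1.5))
  expect_length(rr_intervals(beat_series(200, fs = 200)), 0L)
})

test_that("neighborhood RR statistics are exact on a metronomic train", {
  beats <- beat_series(seq(0, by = 200, length.out = 40), fs = 200)
  rec <- ecg_record(numeric(8000), fs = 200)
  f <- extract_beat_features(rec, beats)
  inner <- 12:28
  expect_true(all(abs(f$rr_mean_20[inner] - 1) < 1e-12))
  expect_true(all(f$rr_sd_20[inner] == 0))
  expect_true(is.na(f$rr_prev[1]))
  expect_true(is.na(f$rr_next[40]))
})

test_that("measured QRS duration matches a dense-grid slope-threshold oracle", {
  # oracle: the same 10%-of-peak-slope, 20 ms-hold definition evaluated on
  # the analytic template derivative at 4 kHz
  waves <- list(c(-0.026, -0.08, 0.009), c(0, 1, 0.011),
                c(0.026, -0.14, 0.009))
  tg <- seq(-0.3, 0.3, by = 1 / 4000)
  f <- Reduce(`+`, lapply(waves, function(w)
    w[2] * exp(-(tg - w[1])^2 / (2 * w[3]^2))))
  dsig <- abs(diff(f)) * 4000
  pk <- max(dsig)
  below <- dsig < 0.1 * pk
  scan_out <- function(dir) {
    ctr <- which.min(abs(tg)); run <- 0; i <- ctr
    repeat {
      i <- i + dir
      if (i < 1 || i > length(dsig)) return(tg[i - dir])
      if (below[i]) {
        run <- run + 1
        if (run >= 0.020 * 4000) return(tg[i - dir * (run - 1)])
      } else run <- 0
    }
  }
  oracle_width <- scan_out(1) - scan_out(-1)

  t <- (0:399) / 200
  sig <- Reduce(`+`, lapply(waves, function(w)
    w[2] * exp(-(t - 1 - w[1])^2 / (2 * w[3]^2))))
  feats <- extract_beat_features(ecg_record(sig, fs = 200),
                                 beat_series(200, fs = 200))
  expect_lt(abs(feats$qrs_duration - oracle_width), 0.010)
})

test_that("P waves are found on sinus beats and absent flags are NA", {
  s <- synth_record(synth_config(rhythm_plan = plan_segment("SINUS", 30),
                                 vpc_rate = 4, seed = 8))
  b <- beat_series(s$annotation$beats$sample, fs = 200)  # truth marks
  f <- extract_beat_features(s$record, b)
  truth_v <- s$annotation$beats$label == "V"
  expect_gte(sum(truth_v), 1L)
  # sinus beats carry a measurable P-R interval near the template's 170 ms
  normal_pr <- f$pr_interval[!truth_v]
  expect_gt(mean(!is.na(normal_pr)), 0.9)
  expect_lt(abs(stats::median(normal_pr, na.rm = TRUE) - 0.17), 0.03)
})
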