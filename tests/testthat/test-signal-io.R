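# Record and annotation I/O: WFDB header/signal pairs, MIT-style binary
# annotations, CSV, the JSON dialect, resampling and windowing. All binary
# fixtures are produced by the package's own writers in tempdir() at test
# time.

test_that("WFDB header fields are echoed into the record", {
  td <- withr::local_tempdir()
  hea <- file.path(td, "echo.hea")
  writeLines(c("echo 1 360 650000",
               "echo.dat 16 200(0)/mV 12 0 0 0 0 MLII"), hea)
  con <- file(file.path(td, "echo.dat"), "wb")
  writeBin(integer(650000), con, size = 2L, endian = "little")
  close(con)
  rec <- read_record(hea)
  expect_equal(rec$fs, 360)
  expect_length(rec$samples, 650000)
  expect_equal(rec$lead_name, "MLII")
})

test_that("CSV sampling rate is inferred from the time column", {
  td <- withr::local_tempdir()
  p <- file.path(td, "two.csv")
  writeLines(c("0,0.0", "0.005,0.1"), p)
  rec <- read_record(p)
  expect_equal(rec$fs, 200)
  expect_equal(rec$samples, c(0, 0.1))
})

test_that("format 212 and 16 round trips preserve digitized samples", {
  td <- withr::local_tempdir()
  s <- synth_record(synth_config(rhythm_plan = plan_segment("SINUS", 15),
                                 seed = 11))
  for (fmt in c(16L, 212L)) {
    p <- file.path(td, paste0("rt", fmt))
    write_record_wfdb(s$record, p, fmt = fmt)
    back <- read_record(paste0(p, ".hea"))
    expect_equal(back$fs, 200)
    expect_length(back$samples, length(s$record$samples))
    # quantization at gain 200 adu/mV is the only loss
    expect_lt(max(abs(back$samples - s$record$samples)), 1 / 200 + 1e-12)
    # re-digitizing the read samples is exact
    write_record_wfdb(back, file.path(td, "again"), fmt = fmt)
    twice <- read_record(file.path(td, "again.hea"))
    expect_identical(twice$samples, back$samples)
  }
})

test_that("unsupported WFDB storage format is a named error", {
  td <- withr::local_tempdir()
  hea <- file.path(td, "bad.hea")
  writeLines(c("bad 1 200 10", "bad.dat 80 200/mV"), hea)
  writeBin(raw(10), file.path(td, "bad.dat"))
  expect_error(read_record(hea), "80")
  expect_error(read_record(file.path(td, "missing.hea")), "not found")
})

test_that("MIT annotations map symbols to AAMI classes and pair rhythms", {
  td <- withr::local_tempdir()
  ann <- ecg_annotation(
    beats = data.frame(sample = c(100, 300, 500), label = c("N", "S", "V")),
    episodes = data.frame(start = 1000, end = 5000, rhythm = "AF"))
  p <- file.path(td, "t.atr")
  write_annotations_mit(ann, p)
  back <- read_annotations(p, n_samples = 6000)
  expect_equal(back$beats$sample, c(100, 300, 500))
  expect_equal(back$beats$label, c("N", "S", "V"))
  af <- back$episodes[back$episodes$rhythm == "AF", ]
  expect_equal(c(af$start, af$end), c(1000, 5000))
})

test_that("a dangling rhythm is closed at the record end", {
  td <- withr::local_tempdir()
  # hand-built stream: one beat, then an (AFIB mark never closed
  con <- file(file.path(td, "d.atr"), "wb")
  w <- function(code, dt) {
    v <- code * 1024L + dt
    writeBin(as.raw(c(bitwAnd(v, 0xFFL), v %/% 256L)), con)
  }
  w(1L, 100L)          # N beat at sample 100
  w(28L, 400L)         # rhythm change at sample 500
  aux <- charToRaw("(AFIB")
  w(63L, length(aux))
  writeBin(c(aux, as.raw(0L)), con)  # pad to even
  w(0L, 0L)
  close(con)
  back <- read_annotations(file.path(td, "d.atr"), n_samples = 2000)
  expect_equal(back$episodes$rhythm, "AF")
  expect_equal(back$episodes$start, 500)
  expect_equal(back$episodes$end, 2000)
})

test_that("an empty annotation stream reads as an empty annotation", {
  td <- withr::local_tempdir()
  p <- file.path(td, "empty.atr")
  writeBin(as.raw(c(0L, 0L)), p)  # EOF word only
  back <- read_annotations(p)
  expect_equal(nrow(back$beats), 0L)
  expect_equal(nrow(back$episodes), 0L)
})

test_that("JSON annotation dialect round trip is lossless", {
  td <- withr::local_tempdir()
  ann <- ecg_annotation(
    beats = data.frame(sample = c(0, 7, 1500), label = c("Q", "S", "V")),
    episodes = data.frame(start = c(0, 900), end = c(800, 1500),
                          rhythm = c("AF", "VF")))
  p <- file.path(td, "a.json")
  write_annotations_json(ann, p)
  back <- read_annotations(p)
  expect_identical(back$beats, ann$beats)
  expect_identical(back$episodes, ann$episodes)
})

test_that("resampling hits the exact target length and is identity at fs", {
  rec <- ecg_record(stats::rnorm(65000), fs = 360, record_id = "r")
  out <- resample_record(rec, 200)
  expect_equal(length(out$samples), round(65000 * 200 / 360))
  expect_identical(resample_record(rec, 360)$samples, rec$samples)
  empty <- resample_record(ecg_record(numeric(), fs = 360), 200)
  expect_length(empty$samples, 0L)
  expect_equal(empty$fs, 200)
})

test_that("resampling preserves the dominant frequency of a sinusoid", {
  fs <- 360
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- ecg_record(sin(2 * pi * 4 * t), fs = fs)
  out <- resample_record(rec, 200)
  sp <- Mod(stats::fft(out$samples))^2
  half <- floor(length(out$samples) / 2)
  fdom <- (which.max(sp[2:half])) * 200 / length(out$samples)
  expect_lt(abs(fdom - 4), 200 / length(out$samples) + 1e-9)  # within 1 bin
})

test_that("annotation rescaling follows the sample-rate ratio", {
  ann <- ecg_annotation(beats = data.frame(sample = c(360, 720),
                                           label = c("N", "N")),
                        episodes = data.frame(start = 0, end = 3600,
                                              rhythm = "AF"))
  out <- rescale_annotations(ann, fs = 360, target_fs = 200)
  expect_equal(out$beats$sample, c(200, 400))
  expect_equal(c(out$episodes$start, out$episodes$end), c(0, 2000))
})

test_that("windowing keeps long partials, drops short tails, and loses nothing", {
  fs <- 200
  rec30 <- ecg_record(stats::rnorm(30 * 60 * fs), fs = fs)
  w <- slice_windows(rec30)
  expect_length(w, 6L)
  expect_true(all(vapply(w, function(x) length(x$samples), numeric(1)) == 60000))
  expect_false(any(vapply(w, attr, logical(1), "partial")))

  rec310 <- ecg_record(stats::rnorm(310 * fs), fs = fs)
  w2 <- slice_windows(rec310)
  expect_length(w2, 1L)   # 10-s remainder dropped
  expect_equal(length(attr(w2, "tail")$samples), 10 * fs)

  rec380 <- ecg_record(stats::rnorm(380 * fs), fs = fs)
  w3 <- slice_windows(rec380)
  expect_length(w3, 2L)
  expect_true(attr(w3[[2]], "partial"))

  expect_length(slice_windows(ecg_record(numeric(), fs = fs)), 0L)

  # concatenation of windows plus tail reconstructs the record
  rebuilt <- c(unlist(lapply(w2, `[[`, "samples")),
               attr(w2, "tail")$samples)
  expect_identical(rebuilt, rec310$samples)
})
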