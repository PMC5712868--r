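# EC57-style beat matching, episode/duration statistics, aggregation.

ann_of <- function(samples, labels) {
  ecg_annotation(beats = data.frame(sample = samples, label = labels))
}

test_that("identical streams score perfectly", {
  a <- ann_of(c(100, 300, 500), c("V", "N", "V"))
  m <- match_beats(a, a, "V", fs = 200)
  st <- beat_stats(m)
  expect_equal(st[["se"]], 100)
  expect_equal(st[["pp"]], 100)
  expect_equal(st[["fpr"]], 0)
})

test_that("the hand-counted mismatch example scores as counted", {
  ref <- ann_of(c(100, 300, 500), c("V", "V", "V"))
  test <- ann_of(c(110, 700), c("V", "V"))
  m <- match_beats(ref, test, "V", fs = 200, tolerance_s = 30 / 200)
  expect_equal(m$tp, 1)
  expect_equal(m$fn, 2)
  expect_equal(m$fp, 1)
  st <- beat_stats(m)
  expect_equal(st[["se"]], 100 / 3, tolerance = 1e-9)
  expect_equal(st[["pp"]], 50)
})

test_that("an empty test stream gives zero Se and undefined +P", {
  ref <- ann_of(c(100, 300), c("V", "V"))
  m <- match_beats(ref, ecg_annotation(), "V", fs = 200)
  st <- beat_stats(m)
  expect_equal(st[["se"]], 0)
  expect_true(is.na(st[["pp"]]))
})

test_that("pairing is one-to-one: a test beat matches at most one reference", {
  ref <- ann_of(c(100, 110), c("V", "V"))
  test <- ann_of(105, "V")
  m <- match_beats(ref, test, "V", fs = 200, tolerance_s = 0.15)
  expect_equal(m$tp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$fp, 0)
})

test_that("swapping reference and test swaps Se with +P", {
  set.seed(8)
  for (rep in 1:10) {
    r <- sort(sample.int(20000, 25))
    t <- sort(sample.int(20000, 20))
    ref <- ann_of(r, sample(c("V", "N"), 25, replace = TRUE))
    test <- ann_of(t, sample(c("V", "N"), 20, replace = TRUE))
    m1 <- beat_stats(match_beats(ref, test, "V", fs = 200))
    m2 <- beat_stats(match_beats(test, ref, "V", fs = 200))
    expect_equal(m1[["se"]], m2[["pp"]])
    expect_equal(m1[["pp"]], m2[["se"]])
  }
})

test_that("episode/duration statistics match hand computations", {
  fs <- 1  # seconds as samples for readability
  ref <- data.frame(start = 60, end = 120)
  test <- data.frame(start = 90, end = 150)
  s <- episode_duration_stats(ref, test)
  expect_equal(c(s$ese, s$epp, s$dse, s$dpp), c(100, 100, 50, 50))

  s2 <- episode_duration_stats(data.frame(start = 0, end = 10),
                               data.frame(start = 20, end = 30))
  expect_equal(c(s2$ese, s2$epp, s2$dse, s2$dpp), c(0, 0, 0, 0))

  s3 <- episode_duration_stats(ref, ref)
  expect_equal(c(s3$ese, s3$epp, s3$dse, s3$dpp), c(100, 100, 100, 100))

  expect_error(
    episode_duration_stats(data.frame(start = c(0, 5), end = c(10, 15)),
                           test), "overlapping")
})

test_that("undefined episode statistics are NA, not zero", {
  none <- data.frame(start = numeric(), end = numeric())
  s <- episode_duration_stats(none, data.frame(start = 0, end = 10))
  expect_true(is.na(s$ese))
  expect_true(is.na(s$dse))
  expect_equal(s$epp, 0)
})

test_that("episode statistics agree with a per-sample brute-force counter", {
  set.seed(17)
  n <- 2000
  for (rep in 1:200) {
    ref <- random_episode_set(n)
    test <- random_episode_set(n)
    if (!nrow(ref) || !nrow(test)) next
    s <- episode_duration_stats(ref, test)
    o <- episode_stats_persample(ref, test, n)
    expect_equal(c(s$ese, s$epp, s$dse, s$dpp),
                 c(o$ese, o$epp, o$dse, o$dpp), tolerance = 1e-12)
  }
})

test_that("gross pools counts while average means per-record statistics", {
  m1 <- structure(list(tp = 1, fp = 0, fn = 1, tn = 10, cls = "V",
                       tolerance_s = 0.15), class = "beat_match")
  m2 <- structure(list(tp = 3, fp = 0, fn = 0, tn = 10, cls = "V",
                       tolerance_s = 0.15), class = "beat_match")
  rep_both <- ec57_aggregate(list(m1, m2))
  expect_equal(rep_both$gross[["se"]], 80)
  expect_equal(rep_both$average[["se"]], 75)

  one <- ec57_aggregate(list(m1))
  expect_equal(one$gross[["se"]], one$average[["se"]])

  # a record with no reference positives is excluded from the average Se
  # but its counts still enter the gross denominator
  m0 <- structure(list(tp = 0, fp = 2, fn = 0, tn = 10, cls = "V",
                       tolerance_s = 0.15), class = "beat_match")
  r <- ec57_aggregate(list(m1, m0))
  expect_equal(r$average[["se"]], 50)
  expect_equal(r$gross[["se"]], 50)   # 1/(1+1), m0 adds nothing to Se
  expect_equal(r$gross[["pp"]], 100 * 1 / 3)
})

test_that("gross Se lies between the per-record extremes", {
  set.seed(23)
  for (rep in 1:20) {
    ms <- lapply(1:4, function(i) {
      tp <- sample.int(50, 1); fn <- sample.int(20, 1)
      structure(list(tp = tp, fp = 0, fn = fn, tn = 0, cls = "V",
                     tolerance_s = 0.15), class = "beat_match")
    })
    r <- ec57_aggregate(ms)
    per <- r$per_record[, "se"]
    expect_gte(r$gross[["se"]], min(per) - 1e-9)
    expect_lte(r$gross[["se"]], max(per) + 1e-9)
  }
})

test_that("report tables carry per-record, Gross and Average rows", {
  m1 <- structure(list(tp = 1, fp = 0, fn = 1, tn = 10, cls = "V",
                       tolerance_s = 0.15), class = "beat_match")
  tab <- ec57_table(ec57_aggregate(list(m1, m1)), c("rec-a", "rec-b"))
  expect_equal(rownames(tab), c("rec-a", "rec-b", "Gross", "Average"))
  td <- withr::local_tempdir()
  p <- write_ec57_report(ec57_aggregate(list(m1)), file.path(td, "r.csv"))
  expect_true(file.exists(p))
})
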