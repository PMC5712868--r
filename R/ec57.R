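# EC57-style scoring of a test annotation stream against a reference:
# beat-level sensitivity / positive predictivity / false positive rate for
# a target AAMI class, and episode/duration statistics for AF and VF
# rhythms, with gross (pooled counts) and average (mean of per-record
# statistics) aggregation. Undefined statistics are NA, flagged and
# excluded from averages, never zero-filled.

#' Match test beats against reference beats
#'
#' Greedy nearest-neighbor one-to-one pairing of all reference and test
#' beats within `tolerance_s`, then per-class confusion counts for the
#' target class: `tp` = pairs labeled `cls` on both sides; `fp` = test
#' `cls` beats unpaired or paired to a non-`cls` reference; `fn` =
#' reference `cls` beats unpaired or paired to a non-`cls` test beat;
#' `tn` = pairs labeled non-`cls` on both sides.
#'
#' @param ref,test [ecg_annotation()] objects on the same time base.
#' @param cls Target class, `"S"` or `"V"` (any label works).
#' @param fs Sampling rate (Hz) used to convert `tolerance_s` to samples.
#' @param tolerance_s Match window (default 0.15 s, the conventional EC57
#'   beat-match window).
#' @return Object of class `beat_match` with `tp`, `fp`, `fn`, `tn`, `cls`,
#'   `tolerance_s`.
#' @export
match_beats <- function(ref, test, cls, fs, tolerance_s = 0.15) {
  rs <- ref$beats$sample; rl <- ref$beats$label
  ts <- test$beats$sample; tl <- test$beats$label
  tol <- tolerance_s * fs
  pairs <- .greedy_pairs(rs, ts, tol)
  ref_paired <- rep(NA_integer_, length(rs))
  ref_paired[pairs[, 1L]] <- pairs[, 2L]
  test_paired <- rep(NA_integer_, length(ts))
  test_paired[pairs[, 2L]] <- pairs[, 1L]

  ref_is <- rl == cls; test_is <- tl == cls
  tp <- sum(ref_is & !is.na(ref_paired) & test_is[ref_paired], na.rm = TRUE)
  fn <- sum(ref_is) - tp
  fp <- sum(test_is) - tp
  tn <- sum(!ref_is & !is.na(ref_paired) & !test_is[ref_paired], na.rm = TRUE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, cls = cls,
                 tolerance_s = tolerance_s),
            class = "beat_match")
}

# greedy one-to-one pairing by increasing |dt| within tolerance
.greedy_pairs <- function(rs, ts, tol) {
  if (!length(rs) || !length(ts))
    return(matrix(integer(), ncol = 2L))
  cand_i <- integer(); cand_j <- integer(); cand_d <- numeric()
  # test beats are >= refractory apart, so few candidates per reference beat
  lo <- findInterval(rs - tol, ts) + 1L
  hi <- findInterval(rs + tol, ts)
  for (i in seq_along(rs)) {
    if (lo[i] > hi[i]) next
    js <- lo[i]:hi[i]
    cand_i <- c(cand_i, rep(i, length(js)))
    cand_j <- c(cand_j, js)
    cand_d <- c(cand_d, abs(ts[js] - rs[i]))
  }
  if (!length(cand_i)) return(matrix(integer(), ncol = 2L))
  o <- order(cand_d)
  used_r <- rep(FALSE, length(rs)); used_t <- rep(FALSE, length(ts))
  out_i <- integer(); out_j <- integer()
  for (k in o) {
    i <- cand_i[k]; j <- cand_j[k]
    if (!used_r[i] && !used_t[j]) {
      used_r[i] <- TRUE; used_t[j] <- TRUE
      out_i <- c(out_i, i); out_j <- c(out_j, j)
    }
  }
  cbind(out_i, out_j)
}

#' Beat statistics from a match
#'
#' @param m A `beat_match`.
#' @return Named numeric vector `se`, `pp`, `fpr` in percent (`NA` when the
#'   denominator is zero).
#' @export
beat_stats <- function(m) {
  c(se = .pct(m$tp, m$tp + m$fn),
    pp = .pct(m$tp, m$tp + m$fp),
    fpr = .pct(m$fp, m$fp + m$tn))
}

.pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Episode and duration statistics for one rhythm
#'
#' Compares same-rhythm half-open episode sets. An episode "hits" when it
#' overlaps any episode of the other stream by at least one sample.
#' `ESe` = hit reference episodes / reference episodes; `E+P` = hit test
#' episodes / test episodes; `DSe` = total overlapped duration / total
#' reference duration; `D+P` = total overlapped duration / total test
#' duration. Zero denominators give `NA`.
#'
#' @param ref_eps,test_eps Data frames with `start`, `end` (half-open) and
#'   optionally `rhythm` columns.
#' @param rhythm Rhythm to score (rows of other rhythms are dropped);
#'   `NULL` scores all rows.
#' @return Object of class `episode_stats`: the four statistics (percent)
#'   plus the raw counts and durations used to pool across records.
#' @export
episode_duration_stats <- function(ref_eps, test_eps, rhythm = NULL) {
  sel <- function(d) {
    if (!is.null(rhythm) && "rhythm" %in% names(d))
      d <- d[d$rhythm == rhythm, , drop = FALSE]
    if (nrow(d) && any(d$start >= d$end)) stop("invalid episode interval")
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping episodes within one stream")
    d
  }
  r <- sel(ref_eps); t <- sel(test_eps)
  ov <- 0
  r_hit <- rep(FALSE, nrow(r)); t_hit <- rep(FALSE, nrow(t))
  for (i in seq_len(nrow(r))) for (j in seq_len(nrow(t))) {
    o <- min(r$end[i], t$end[j]) - max(r$start[i], t$start[j])
    if (o > 0) {
      ov <- ov + o
      r_hit[i] <- TRUE; t_hit[j] <- TRUE
    }
  }
  ref_dur <- sum(r$end - r$start); test_dur <- sum(t$end - t$start)
  structure(list(
    ese = .pct(sum(r_hit), nrow(r)), epp = .pct(sum(t_hit), nrow(t)),
    dse = .pct(ov, ref_dur), dpp = .pct(ov, test_dur),
    n_ref = nrow(r), n_ref_hit = sum(r_hit),
    n_test = nrow(t), n_test_hit = sum(t_hit),
    overlap = ov, ref_dur = ref_dur, test_dur = test_dur,
    rhythm = if (is.null(rhythm)) NA_character_ else rhythm),
    class = "episode_stats")
}

#' Aggregate per-record scores
#'
#' Gross statistics pool the numerators and denominators over records
#' before dividing; average statistics are unweighted means of the
#' per-record statistics, skipping records where a statistic is undefined.
#' Works on a list of `beat_match` objects (giving `se`, `pp`, `fpr`) or of
#' `episode_stats` objects (giving `ese`, `epp`, `dse`, `dpp`).
#'
#' @param per_record List of `beat_match` or `episode_stats`, one per
#'   record.
#' @param mode `"gross"`, `"average"`, or `"both"` (default).
#' @return Object of class `ec57_report`: per-record statistics plus the
#'   requested aggregate rows, all in percent.
#' @export
ec57_aggregate <- function(per_record, mode = c("both", "gross", "average")) {
  mode <- match.arg(mode)
  if (!length(per_record)) stop("need at least one record")
  is_beat <- inherits(per_record[[1L]], "beat_match")
  if (is_beat) {
    per <- t(vapply(per_record, beat_stats, numeric(3L)))
    tp <- sum(vapply(per_record, `[[`, numeric(1L), "tp"))
    fp <- sum(vapply(per_record, `[[`, numeric(1L), "fp"))
    fn <- sum(vapply(per_record, `[[`, numeric(1L), "fn"))
    tn <- sum(vapply(per_record, `[[`, numeric(1L), "tn"))
    gross <- c(se = .pct(tp, tp + fn), pp = .pct(tp, tp + fp),
               fpr = .pct(fp, fp + tn))
  } else {
    per <- t(vapply(per_record, function(s)
      c(ese = s$ese, epp = s$epp, dse = s$dse, dpp = s$dpp), numeric(4L)))
    tot <- function(f) sum(vapply(per_record, `[[`, numeric(1L), f))
    gross <- c(ese = .pct(tot("n_ref_hit"), tot("n_ref")),
               epp = .pct(tot("n_test_hit"), tot("n_test")),
               dse = .pct(tot("overlap"), tot("ref_dur")),
               dpp = .pct(tot("overlap"), tot("test_dur")))
  }
  avg <- colMeans(per, na.rm = TRUE)
  avg[colSums(!is.na(per)) == 0L] <- NA_real_
  structure(list(per_record = per,
                 gross = if (mode != "average") gross else NULL,
                 average = if (mode != "gross") avg else NULL,
                 mode = mode, kind = if (is_beat) "beat" else "episode"),
            class = "ec57_report")
}

#' @export
print.ec57_report <- function(x, digits = 2, ...) {
  cat(sprintf("<ec57_report> %s statistics, %d record(s)\n", x$kind,
              nrow(x$per_record)))
  print(round(as.data.frame(ec57_table(x)), digits))
  invisible(x)
}

#' Tabulate an EC57 report
#'
#' Per-record rows followed by `Gross` and `Average` rows, mirroring the
#' usual database-evaluation table layout.
#'
#' @param report An `ec57_report`.
#' @param record_ids Optional row names for the per-record rows.
#' @return A data frame (percent values; NA = undefined).
#' @export
ec57_table <- function(report, record_ids = NULL) {
  tab <- as.data.frame(report$per_record)
  rownames(tab) <- record_ids %||% sprintf("record_%d", seq_len(nrow(tab)))
  if (!is.null(report$gross)) tab <- rbind(tab, Gross = report$gross)
  if (!is.null(report$average)) tab <- rbind(tab, Average = report$average)
  tab
}

#' Write an EC57 report as CSV or JSON
#'
#' @param report An `ec57_report`.
#' @param path Output path; format chosen by the `.csv` / `.json`
#'   extension.
#' @param record_ids Optional per-record row labels.
#' @return `path`, invisibly.
#' @export
write_ec57_report <- function(report, path, record_ids = NULL) {
  tab <- ec57_table(report, record_ids)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cbind(row = rownames(tab), tab), path,
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(tab, path, row.names = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
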