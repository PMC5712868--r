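# Atrial-fibrillation detection per 5-minute window from the
# ectopy-corrected RR series. The RR series is converted to instantaneous
# heart rate, quantized to a 64-level symbolic sequence (5 bpm bins,
# saturating at 315 bpm), encoded as overlapping 3-symbol base-64 word
# values, and the irregularity of the word-value sequence is measured by
# sample entropy. AF is declared when the window's sample entropy reaches a
# calibrated threshold.

#' Correct RR intervals around ventricular ectopic beats
#'
#' Ventricular premature complexes distort the RR series (short coupling
#' interval plus compensatory pause) and would mimic AF irregularity. For
#' every beat labeled `V`, both adjacent intervals are replaced by the mean
#' of the nearest intervals on either side that are not themselves adjacent
#' to an ectopic beat; at record edges the single available neighbor is
#' used. Non-adjacent intervals are returned bit-identical.
#'
#' @param rr RR intervals (s), `length(labels) - 1` of them.
#' @param labels Per-beat labels; `"V"` marks ectopic beats.
#' @return Corrected RR vector of the same length.
#' @examples
#' correct_rr(c(0.8, 0.8, 0.5, 1.1), c("N", "N", "V", "N", "N"))
#' # -> 0.80 0.95 0.95 1.10
#' @export
correct_rr <- function(rr, labels) {
  if (length(rr) != length(labels) - 1L)
    stop("need length(rr) == length(labels) - 1")
  n <- length(rr)
  if (n == 0L) return(rr)
  v <- which(labels == "V")
  if (!length(v)) return(rr)
  # interval i sits between beats i and i+1: a V at beat b touches
  # intervals b-1 and b
  bad <- rep(FALSE, n)
  for (b in v) {
    if (b - 1L >= 1L && b - 1L <= n) bad[b - 1L] <- TRUE
    if (b >= 1L && b <= n) bad[b] <- TRUE
  }
  if (all(bad)) {
    warning("all intervals adjacent to ectopic beats; RR returned unchanged")
    return(rr)
  }
  out <- rr
  i <- 1L
  while (i <= n) {
    if (bad[i]) {
      j <- i
      while (j < n && bad[j + 1L]) j <- j + 1L
      left <- if (i > 1L) rr[i - 1L] else NA_real_
      right <- if (j < n) rr[j + 1L] else NA_real_
      repl <- mean(c(left, right), na.rm = TRUE)
      out[i:j] <- repl
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Instantaneous heart rate from RR intervals
#'
#' @param rr RR intervals in seconds, all positive.
#' @return Heart rates in beats per minute, `60 / rr`.
#' @export
rr_to_hr <- function(rr) {
  if (length(rr) && any(rr <= 0)) stop("RR intervals must be positive")
  60 / rr
}

#' Symbolize heart rates
#'
#' Quantizes each heart rate to a 6-bit symbol: 5-bpm bins saturating at the
#' top bin, `sy = 63` when `hr >= 315`, otherwise `floor(hr / 5)`.
#'
#' @param hr Heart rates (bpm), nonnegative.
#' @return Integer symbols in 0..63.
#' @examples
#' symbolize(c(60, 314, 315))  # 12 62 63
#' @export
symbolize <- function(hr) {
  if (length(hr) && any(hr < 0)) stop("heart rates must be nonnegative")
  as.integer(ifelse(hr >= 315, 63L, floor(hr / 5)))
}

#' Word values of a symbolic sequence
#'
#' Encodes each overlapping triple of consecutive symbols as a base-64
#' positional code: `wv_n = sy_{n-2} * 2^12 + sy_{n-1} * 2^6 + sy_n`. The
#' encoding is injective on symbol triples; values range over 0..262143.
#'
#' @param sy Integer symbols in 0..63.
#' @return Integer word values, length `length(sy) - 2` (empty when fewer
#'   than 3 symbols).
#' @examples
#' word_values(c(12, 12, 12))  # 49932
#' @export
word_values <- function(sy) {
  if (length(sy) && (any(sy < 0) || any(sy > 63)))
    stop("symbols must lie in 0..63")
  n <- length(sy)
  if (n < 3L) return(integer())
  as.integer(sy[1:(n - 2L)] * 4096L + sy[2:(n - 1L)] * 64L + sy[3:n])
}

#' Sample entropy
#'
#' `SampEn(m, r)` of a sequence: with `B` the number of pairs of distinct
#' length-`m` templates whose Chebyshev distance is at most `r`, and `A` the
#' same count for length-`m+1` templates (both over the first `N - m`
#' starting positions), `SampEn = -ln(A / B)`. Returns `NA` — explicitly
#' undefined, never 0 — when the sequence is too short or when `A` or `B`
#' is zero.
#'
#' @param x Numeric sequence.
#' @param m Template length (default 2).
#' @param r Chebyshev tolerance (> 0); conventionally a multiple of `sd(x)`.
#' @return Nonnegative entropy estimate, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(x, m = 2L, r) {
  x <- as.numeric(x)
  N <- length(x)
  if (r <= 0) stop("`r` must be positive")
  if (N <= m + 1L) return(NA_real_)
  nt <- N - m  # number of template starting positions
  # Chebyshev distances via running pmax over lag-aligned differences
  D <- abs(outer(x, x, "-"))
  Cm <- D[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1L) for (k in seq_len(m - 1L))
    Cm <- pmax(Cm, D[seq_len(nt) + k, seq_len(nt) + k, drop = FALSE])
  Cm1 <- pmax(Cm, D[seq_len(nt) + m, seq_len(nt) + m, drop = FALSE])
  ut <- upper.tri(Cm)
  B <- sum(Cm[ut] <= r)
  A <- sum(Cm1[ut] <= r)
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

#' Default AF-window parameters
#'
#' @return Named list: `m` (sample-entropy template length, 2), `r_factor`
#'   (tolerance as a fraction of the word-value SD, 0.2), `theta_af`
#'   (entropy threshold 1.22, calibrated once on 20 synthetic AF and 20
#'   sinus windows with `scripts/calibrate_af.R`), `min_beats` (minimum
#'   beats for a determinate decision, 100).
#' @export
af_config <- function() {
  list(m = 2L, r_factor = 0.2, theta_af = 1.22, min_beats = 100L)
}

#' AF decision for one analysis window
#'
#' Runs the RR-dynamics chain on one window of beats: ectopy correction of
#' the RR series ([correct_rr()]), conversion to heart rate, symbolization,
#' word values, and sample entropy of the word-value sequence with
#' `r = r_factor * sd(wv)`. The window is AF when the entropy reaches
#' `theta_af`. The decision is `NA` (undetermined) when fewer than
#' `min_beats` beats are present or the entropy is undefined; a constant
#' word-value sequence has entropy 0 by convention (every template matches).
#'
#' @param beats A [beat_series()] for one window, labels assigned (V beats
#'   drive the RR correction).
#' @param params See [af_config()].
#' @param window_id Identifier carried into the result.
#' @return Object of class `af_decision`: `window_id`, `sampen`, `is_af`
#'   (TRUE/FALSE/NA), `n_beats`, `params`.
#' @export
detect_af_window <- function(beats, params = af_config(), window_id = 1L) {
  n <- length(beats$beat_samples)
  rr <- rr_intervals(beats)
  sampen <- NA_real_
  if (length(rr) >= 3L) {
    rrc <- correct_rr(rr, beats$labels)
    wv <- word_values(symbolize(rr_to_hr(rrc)))
    if (length(wv) > params$m + 1L) {
      s <- stats::sd(wv)
      if (s == 0) {
        sampen <- 0
      } else {
        sampen <- sample_entropy(wv, m = params$m, r = params$r_factor * s)
      }
    }
  }
  is_af <- if (n < params$min_beats || is.na(sampen)) NA else
    sampen >= params$theta_af
  structure(list(window_id = window_id, sampen = sampen, is_af = is_af,
                 n_beats = n, params = params),
            class = "af_decision")
}

#' @export
print.af_decision <- function(x, ...) {
  cat(sprintf("<af_decision> window %s: SampEn %s, AF = %s (%d beats)\n",
              x$window_id,
              if (is.na(x$sampen)) "undefined" else sprintf("%.3f", x$sampen),
              if (is.na(x$is_af)) "undetermined" else x$is_af, x$n_beats))
  invisible(x)
}

#' Calibrate the AF entropy threshold
#'
#' Given window sample entropies for known AF and known non-AF windows,
#' returns the midpoint between the largest non-AF entropy and the smallest
#' AF entropy when the two groups separate; otherwise the threshold
#' maximizing Youden's J over the pooled candidate cut points.
#'
#' @param af_sampen Sample entropies of AF windows.
#' @param sinus_sampen Sample entropies of non-AF windows.
#' @return The calibrated threshold (single number).
#' @export
calibrate_af_threshold <- function(af_sampen, sinus_sampen) {
  af <- af_sampen[!is.na(af_sampen)]
  si <- sinus_sampen[!is.na(sinus_sampen)]
  if (!length(af) || !length(si)) stop("need entropies from both groups")
  if (min(af) > max(si)) return((min(af) + max(si)) / 2)
  cuts <- sort(unique(c(af, si)))
  j <- vapply(cuts, function(th)
    mean(af >= th) + mean(si < th) - 1, numeric(1L))
  cuts[which.max(j)]
}

#' Merge per-window AF decisions into episodes
#'
#' Consecutive AF-positive windows become one episode; window boundaries
#' define the episode boundaries. Undetermined windows break a run.
#'
#' @param decisions List of `af_decision` objects, in window order.
#' @param window_bounds Data frame with `start` and `end` (half-open sample
#'   interval) per window, same order.
#' @return Data frame of AF episodes (`start`, `end`, `rhythm = "AF"`).
#' @export
af_episodes <- function(decisions, window_bounds) {
  pos <- vapply(decisions, function(d) isTRUE(d$is_af), logical(1L))
  if (!any(pos))
    return(data.frame(start = numeric(), end = numeric(),
                      rhythm = character()))
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(start = window_bounds$start[starts[keep]],
             end = window_bounds$end[ends[keep]],
             rhythm = "AF")
}
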