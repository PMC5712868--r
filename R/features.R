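# Per-beat interval and morphology features feeding the premature-beat
# classifiers: P-R interval, QRS duration, previous/next RR, pooled
# mean/SD of the RR intervals around the 10 beats before and after, and
# R-wave amplitude. Undefined quantities are NA, never silently zero.

#' Extract per-beat features
#'
#' Measures, for every beat in `beats`:
#' \describe{
#'   \item{pr_interval}{P-peak to R-peak distance (s). The P wave is searched
#'     40–240 ms before the QRS onset in a smoothed copy of the signal; when
#'     no convincing P deflection exists the value is NA.}
#'   \item{qrs_duration}{QRS onset-to-offset span (s), found by scanning
#'     outward from the R peak until the rectified slope stays below 10\% of
#'     the beat's peak slope for at least 20 ms.}
#'   \item{rr_prev, rr_next}{Adjacent RR intervals (s); NA at record edges.}
#'   \item{rr_mean_20, rr_sd_20}{Mean and SD of the pooled RR intervals
#'     around the 10 beats before and 10 beats after the current beat,
#'     truncated at record edges.}
#'   \item{r_amplitude}{R-peak voltage relative to the local baseline (mV).}
#' }
#'
#' @param rec The [ecg_record()] the beats were detected on.
#' @param beats A [beat_series()] aligned with `rec`.
#' @return Data frame with one row per beat and the columns above.
#' @export
extract_beat_features <- function(rec, beats) {
  fs <- rec$fs
  x <- rec$samples
  idx <- beats$beat_samples + 1  # 1-based
  n <- length(idx)
  out <- data.frame(pr_interval = rep(NA_real_, n),
                    qrs_duration = NA_real_,
                    rr_prev = NA_real_, rr_next = NA_real_,
                    rr_mean_20 = NA_real_, rr_sd_20 = NA_real_,
                    r_amplitude = NA_real_)
  if (n == 0L) return(out)

  rr <- rr_intervals(beats)
  if (n > 1L) {
    out$rr_prev <- c(NA_real_, rr)
    out$rr_next <- c(rr, NA_real_)
  }
  for (i in seq_len(n)) {
    lo <- max(1L, i - 10L); hi <- min(length(rr), i + 9L)
    if (length(rr) && lo <= hi) {
      pool <- rr[lo:hi]
      out$rr_mean_20[i] <- mean(pool)
      out$rr_sd_20[i] <- if (length(pool) > 1L) stats::sd(pool) else 0
    }
  }

  # slope signal for fiducial location; a short central-difference kernel
  # keeps the onset/offset estimates crisp (wider kernels bias the
  # measured QRS duration upward)
  dv <- numeric(length(x))
  if (length(x) >= 3L)
    dv[2:(length(x) - 1L)] <- abs(x[3:length(x)] - x[1:(length(x) - 2L)]) / 2
  smooth <- .moving_average(x, max(1L, round(0.02 * fs)))
  w_on <- round(0.02 * fs)           # 20 ms of sustained low slope
  max_scan <- round(0.12 * fs)       # QRS half-width never exceeds 120 ms

  for (i in seq_len(n)) {
    r <- as.integer(round(idx[i]))
    lo <- max(1L, r - max_scan); hi <- min(length(x), r + max_scan)
    pk_slope <- max(dv[lo:hi])
    if (pk_slope <= 0) next
    onset <- .scan_fiducial(dv, r, -1L, 0.1 * pk_slope, w_on, max_scan)
    offset <- .scan_fiducial(dv, r, +1L, 0.1 * pk_slope, w_on, max_scan)
    if (!is.na(onset) && !is.na(offset))
      out$qrs_duration[i] <- (offset - onset) / fs

    # local baseline: median over the 100 ms preceding the P search window
    base_lo <- max(1L, r - round(0.40 * fs)); base_hi <- max(1L, r - round(0.28 * fs))
    baseline <- stats::median(x[base_lo:base_hi])
    out$r_amplitude[i] <- x[r] - baseline

    if (!is.na(onset)) {
      p_lo <- max(1L, onset - round(0.24 * fs))
      p_hi <- onset - round(0.04 * fs)
      if (p_hi > p_lo + 2L) {
        seg <- smooth[p_lo:p_hi]
        p_rel <- which.max(seg)
        prominence <- seg[p_rel] - stats::median(seg)
        # demand a clear positive deflection to call it a P wave
        if (is.finite(prominence) && prominence > 0.03) {
          p_idx <- p_lo + p_rel - 1L
          out$pr_interval[i] <- (r - p_idx) / fs
        }
      }
    }
  }
  out
}

# scan from r in the given direction until the slope signal stays below
# `level` for `hold` consecutive samples; returns the fiducial index or NA
.scan_fiducial <- function(dv, r, dir, level, hold, max_scan) {
  n <- length(dv)
  run <- 0L
  i <- r
  steps <- 0L
  while (steps <= max_scan) {
    i2 <- i + dir
    if (i2 < 1L || i2 > n) return(i)
    i <- i2
    if (dv[i] < level) {
      run <- run + 1L
      if (run >= hold) return(i - dir * (run - 1L))
    } else {
      run <- 0L
    }
    steps <- steps + 1L
  }
  i
}
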