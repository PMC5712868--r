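# Hamilton-style QRS detection: band-pass, derivative, rectification,
# moving-window integration, then adaptive peak/noise thresholding with
# T-wave rejection and RR-gap search-back. All thresholds are relative to
# running peak estimates, so detection is invariant to positive rescaling
# of the input.

#' Default QRS detector configuration
#'
#' All constants of the detection chain, exposed for tuning:
#' \describe{
#'   \item{bp_low, bp_high}{Band-pass edges (Hz); the QRS energy band.}
#'   \item{mwi_ms}{Moving-window integration length (ms).}
#'   \item{threshold_factor}{Detection threshold position between the running
#'     noise-peak and QRS-peak means (0.3125, i.e. noise + 31.25\% of the
#'     peak-to-noise span).}
#'   \item{refractory_ms}{Minimum spacing between accepted beats (ms).}
#'   \item{twave_ms}{Window after a beat in which a low-slope peak is
#'     rejected as a T wave (ms).}
#'   \item{twave_slope_factor}{A candidate within the T-wave window is
#'     rejected when its maximum absolute slope is below this fraction of the
#'     preceding QRS's.}
#'   \item{searchback_factor}{A gap longer than this multiple of the running
#'     mean RR triggers search-back at half threshold.}
#'   \item{n_running}{Number of recent peaks kept in the running means.}
#' }
#'
#' @return Named list of detector parameters.
#' @export
qrs_config <- function() {
  list(bp_low = 8, bp_high = 16, mwi_ms = 80,
       threshold_factor = 0.3125,
       refractory_ms = 200,
       twave_ms = 360, twave_slope_factor = 0.5,
       searchback_factor = 1.5,
       n_running = 8)
}

#' Detect QRS complexes
#'
#' Runs the Hamilton-style detection chain on a record (expected at the
#' pipeline's 200 Hz working rate; any rate works, constants are specified in
#' time units). Returns the detected R-peak locations as a [beat_series()]
#' with labels initialized to `"unknown"`. Records shorter than 2 s return an
#' empty series.
#'
#' @param rec An [ecg_record()].
#' @param config Detector constants, see [qrs_config()].
#' @return A [beat_series()] of R-peak sample indices (0-based).
#' @examples
#' rec <- synth_record(synth_config(rhythm_plan = plan_segment("SINUS", 30),
#'                                  seed = 1))$record
#' detect_qrs(rec)
#' @export
detect_qrs <- function(rec, config = qrs_config()) {
  fs <- rec$fs
  x <- rec$samples
  if (length(x) < 2 * fs) return(beat_series(numeric(), fs = fs))

  bp <- .qrs_bandpass(x, fs, config)
  dv <- .qrs_derivative(bp)
  mwi <- .moving_average(abs(dv), max(1L, round(config$mwi_ms / 1000 * fs)))

  pk <- .local_maxima(mwi)
  if (!length(pk)) return(beat_series(numeric(), fs = fs))
  pkv <- mwi[pk]

  refr <- round(config$refractory_ms / 1000 * fs)
  twin <- round(config$twave_ms / 1000 * fs)
  tf <- config$threshold_factor
  nrun <- config$n_running

  # learning phase: seed the running estimates from the first 2 s
  lead_in <- pkv[pk <= 2 * fs]
  qpk_hist <- if (length(lead_in)) max(lead_in) else max(pkv)
  npk_hist <- if (length(lead_in)) stats::median(lead_in) else 0
  qrs_idx <- integer()
  qrs_slope <- numeric()
  rr_hist <- numeric()
  last_checked <- 0L

  slope_at <- function(i) {
    lo <- max(1L, i - round(0.05 * fs)); hi <- min(length(dv), i + round(0.05 * fs))
    max(abs(dv[lo:hi]))
  }
  thr <- function() {
    npk <- mean(utils::tail(npk_hist, nrun))
    qpk <- mean(utils::tail(qpk_hist, nrun))
    npk + tf * (qpk - npk)
  }

  k <- 1L
  while (k <= length(pk)) {
    i <- pk[k]; v <- pkv[k]
    accept <- FALSE
    if (v > thr() && v > 0) {
      if (!length(qrs_idx) || i - qrs_idx[length(qrs_idx)] > refr) {
        accept <- TRUE
        # T-wave rejection: low-slope peak soon after the previous beat
        if (length(qrs_idx) &&
            i - qrs_idx[length(qrs_idx)] < twin &&
            slope_at(i) < config$twave_slope_factor *
              qrs_slope[length(qrs_slope)])
          accept <- FALSE
      }
    }
    if (accept) {
      if (length(qrs_idx))
        rr_hist <- c(rr_hist, i - qrs_idx[length(qrs_idx)])
      qrs_idx <- c(qrs_idx, i)
      qrs_slope <- c(qrs_slope, slope_at(i))
      qpk_hist <- c(qpk_hist, v)
      last_checked <- k
    } else if (v > 0) {
      npk_hist <- c(npk_hist, v)
    }
    # search-back: long RR gap -> revisit skipped peaks at half threshold
    if (length(rr_hist) >= 2L && length(qrs_idx)) {
      mean_rr <- mean(utils::tail(rr_hist, nrun))
      gap <- i - qrs_idx[length(qrs_idx)]
      if (gap > config$searchback_factor * mean_rr) {
        cand <- which(pk > qrs_idx[length(qrs_idx)] + refr & pk < i &
                        pkv > thr() / 2)
        if (length(cand)) {
          b <- cand[which.max(pkv[cand])]
          j <- pk[b]
          if (j - qrs_idx[length(qrs_idx)] > refr && i - j > refr) {
            rr_hist <- c(rr_hist, j - qrs_idx[length(qrs_idx)])
            qrs_idx <- c(qrs_idx, j)
            qrs_slope <- c(qrs_slope, slope_at(j))
            qpk_hist <- c(qpk_hist, pkv[b])
            # re-examine current peak against the updated state
            next
          }
        }
      }
    }
    k <- k + 1L
  }

  if (!length(qrs_idx)) return(beat_series(numeric(), fs = fs))
  r_peaks <- vapply(qrs_idx, function(i) .refine_r_peak(bp, i, fs), numeric(1L))
  r_peaks <- sort(unique(r_peaks))
  # enforce refractory after refinement
  if (length(r_peaks) > 1L) {
    keep <- c(TRUE, diff(r_peaks) >= refr)
    r_peaks <- r_peaks[keep]
  }
  beat_series(r_peaks - 1, fs = fs)  # 0-based
}

# centered, zero-phase 8-16 Hz band-pass
.qrs_bandpass <- function(x, fs, config) {
  ny <- fs / 2
  bf <- signal::butter(2, c(config$bp_low, config$bp_high) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# 5-point central derivative, zero lag
.qrs_derivative <- function(x) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 5L)
    d[3:(n - 2)] <- (2 * x[5:n] + x[4:(n - 1)] -
                       x[2:(n - 3)] - 2 * x[1:(n - 4)]) / 8
  d
}

.moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# indices of strict local maxima (plateau centers)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  up <- c(FALSE, diff(x) > 0)
  down <- c(diff(x) < 0, FALSE)
  # peak: last rising sample followed (possibly after a plateau) by a fall
  cand <- which(up & c(x[-1] <= x[-n], TRUE))
  cand[cand > 1L & cand < n]
}

# locate the R peak as the extremum of the band-passed signal near the
# integrated-energy peak
.refine_r_peak <- function(bp, i, fs) {
  w <- round(0.10 * fs)
  lo <- max(1L, i - w); hi <- min(length(bp), i + w)
  seg <- bp[lo:hi]
  lo + which.max(abs(seg)) - 1L
}
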