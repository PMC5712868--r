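# Ventricular-fibrillation detection per 2-second segment. VF shows a
# narrow-band oscillation with dominant frequency of a few Hz and no
# discrete QRS complexes, so each segment is classified from the ratio of
# the peak periodogram power in a VF band [2.61, 4.95] Hz to the summed
# peak powers of the flanking non-VF bands (0.5, 2.61) and (4.95, 10] Hz,
# against a fixed ratio threshold of 3.96.

#' Default VF detector parameters
#'
#' @return Named list: `seg_s` (segment length, 2 s), `band_vf`
#'   (`[2.61, 4.95]` Hz, inclusive), `band_nvf` (`(0.5, 2.61)` Hz, open),
#'   `band_nvf2` (`(4.95, 10]` Hz), `threshold` (ratio threshold, 3.96;
#'   inclusive — a tie counts as VF), `bridge_gaps` (number of consecutive
#'   negative segments bridged inside an episode, 1).
#' @export
vf_config <- function() {
  list(seg_s = 2, band_vf = c(2.61, 4.95), band_nvf = c(0.5, 2.61),
       band_nvf2 = c(4.95, 10), threshold = 3.96, bridge_gaps = 1L)
}

#' Cut a record into consecutive 2-s segments
#'
#' Non-overlapping segments of `seg_s` seconds (400 samples at the 200 Hz
#' working rate); a trailing remainder shorter than a full segment is
#' discarded.
#'
#' @param rec An [ecg_record()].
#' @param seg_s Segment length in seconds (default 2).
#' @return List of numeric sample vectors; each carries a `start_sample`
#'   attribute (0-based offset into `rec`).
#' @export
segment_2s <- function(rec, seg_s = 2) {
  slen <- round(seg_s * rec$fs)
  n_seg <- length(rec$samples) %/% slen
  lapply(seq_len(n_seg), function(k) {
    s <- rec$samples[((k - 1L) * slen + 1L):(k * slen)]
    attr(s, "start_sample") <- (k - 1L) * slen
    s
  })
}

#' Periodogram band peaks of one segment
#'
#' Removes the segment mean, computes the raw (rectangular-window,
#' unpadded) periodogram `|FFT|^2 / n`, and takes the maximum periodogram
#' value over the bins falling in each of the three bands. With 400 samples
#' at 200 Hz the bin spacing is 0.5 Hz, so the VF band [2.61, 4.95] Hz
#' contains the bins 3.0–4.5 Hz. Peak values below a relative numerical
#' floor (1e-9 of the largest non-DC bin) are clamped to zero so that
#' spectral leakage at machine-precision level cannot produce a spurious
#' ratio.
#'
#' @param segment Numeric sample vector (one 2-s segment).
#' @param fs Sampling rate (default 200 Hz).
#' @param config See [vf_config()].
#' @return Object of class `spectral_bands`: `p_vf`, `p_nvf`, `p_nvf2`,
#'   `ratio` (`p_vf / (p_nvf + p_nvf2)`, `Inf` when the denominator is 0
#'   with positive `p_vf`, 0 when everything is 0), `threshold`.
#' @export
band_peaks <- function(segment, fs = 200, config = vf_config()) {
  x <- as.numeric(segment)
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / n
  half <- floor(n / 2)
  freq <- (0:half) * fs / n
  P <- P[1:(half + 1L)]
  floor_val <- if (half >= 1L) 1e-9 * max(P[-1L]) else 0
  pk <- function(in_band) {
    v <- if (any(in_band)) max(P[in_band]) else 0
    if (v <= floor_val) 0 else v
  }
  p_vf <- pk(freq >= config$band_vf[1L] & freq <= config$band_vf[2L])
  p_nvf <- pk(freq > config$band_nvf[1L] & freq < config$band_nvf[2L])
  p_nvf2 <- pk(freq > config$band_nvf2[1L] & freq <= config$band_nvf2[2L])
  den <- p_nvf + p_nvf2
  ratio <- if (den > 0) p_vf / den else if (p_vf > 0) Inf else 0
  structure(list(p_vf = p_vf, p_nvf = p_nvf, p_nvf2 = p_nvf2,
                 ratio = ratio, threshold = config$threshold),
            class = "spectral_bands")
}

#' @export
print.spectral_bands <- function(x, ...) {
  cat(sprintf("<spectral_bands> p_vf %.3g, p_nVF %.3g, p_nVF2 %.3g, ratio %.3g (thr %.2f)\n",
              x$p_vf, x$p_nvf, x$p_nvf2, x$ratio, x$threshold))
  invisible(x)
}

#' Classify one segment as VF or not
#'
#' VF iff the band-peak ratio reaches the threshold (inclusive: a ratio of
#' exactly 3.96 is VF). A zero denominator with positive VF-band power is
#' VF; an all-zero spectrum is not.
#'
#' @param bands A `spectral_bands` object from [band_peaks()].
#' @return Logical.
#' @export
classify_vf_segment <- function(bands) {
  bands$ratio >= bands$threshold
}

#' Detect VF episodes over a whole record
#'
#' Classifies every 2-s segment and merges positives into half-open
#' episodes; runs of up to `bridge_gaps` consecutive negative segments
#' between positives are bridged (episode/duration scoring is sensitive to
#' fragmentation).
#'
#' @param rec An [ecg_record()] at the working rate.
#' @param config See [vf_config()].
#' @return List with `episodes` (data frame `start`, `end`, `rhythm="VF"`)
#'   and `segments` (data frame `start_sample`, `ratio`, `is_vf` per
#'   segment).
#' @export
detect_vf <- function(rec, config = vf_config()) {
  segs <- segment_2s(rec, config$seg_s)
  slen <- round(config$seg_s * rec$fs)
  if (!length(segs))
    return(list(episodes = data.frame(start = numeric(), end = numeric(),
                                      rhythm = character()),
                segments = data.frame(start_sample = numeric(),
                                      ratio = numeric(), is_vf = logical())))
  bands <- lapply(segs, band_peaks, fs = rec$fs, config = config)
  is_vf <- vapply(bands, classify_vf_segment, logical(1L))
  ratio <- vapply(bands, function(b) b$ratio, numeric(1L))
  starts <- vapply(segs, attr, numeric(1L), "start_sample")

  merged <- .bridge_runs(is_vf, config$bridge_gaps)
  eps <- data.frame(start = numeric(), end = numeric(), rhythm = character())
  if (any(merged)) {
    runs <- rle(merged)
    hi <- cumsum(runs$lengths); lo <- hi - runs$lengths + 1L
    keep <- which(runs$values)
    eps <- data.frame(start = starts[lo[keep]],
                      end = starts[hi[keep]] + slen,
                      rhythm = "VF")
  }
  list(episodes = eps,
       segments = data.frame(start_sample = starts, ratio = ratio,
                             is_vf = is_vf))
}

# bridge runs of up to `g` FALSE values sandwiched between TRUEs
.bridge_runs <- function(x, g) {
  if (g <= 0L || !any(x)) return(x)
  runs <- rle(x)
  k <- length(runs$values)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      if (!runs$values[j] && runs$lengths[j] <= g &&
          runs$values[j - 1L] && runs$values[j + 1L])
        runs$values[j] <- TRUE
    }
  }
  inverse.rle(runs)
}
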