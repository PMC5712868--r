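# Rate conversion to the pipeline's 200 Hz time base and 5-minute windowing.

#' Resample an ECG record
#'
#' Rational-ratio resampling with polyphase FIR anti-alias filtering
#' (`signal::resample`). The output has exactly `round(n * target_fs / fs)`
#' samples; when `target_fs == fs` the samples are returned unchanged. The
#' anti-alias low-pass is the `signal` package's default polyphase design;
#' its near-linear phase keeps beat fiducials aligned after index rescaling
#' with [rescale_annotations()].
#'
#' @param rec An [ecg_record()].
#' @param target_fs Target sampling rate in Hz (default 200, the pipeline's
#'   working rate).
#' @return An [ecg_record()] at `target_fs`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 4 * seq(0, 5, by = 1/360)), fs = 360)
#' length(resample_record(rec, 200)$samples)
#' @export
resample_record <- function(rec, target_fs = 200) {
  if (target_fs <= 0) stop("`target_fs` must be positive")
  n <- length(rec$samples)
  if (n == 0L)
    return(ecg_record(numeric(), fs = target_fs, record_id = rec$record_id,
                      lead_name = rec$lead_name))
  if (isTRUE(all.equal(target_fs, rec$fs)))
    return(ecg_record(rec$samples, fs = target_fs, record_id = rec$record_id,
                      lead_name = rec$lead_name))
  pq <- .rational_ratio(target_fs, rec$fs)
  y <- signal::resample(rec$samples, p = pq[1L], q = pq[2L])
  n_out <- round(n * target_fs / rec$fs)
  if (length(y) >= n_out) {
    y <- y[seq_len(n_out)]
  } else {
    y <- c(y, rep(y[length(y)], n_out - length(y)))
  }
  ecg_record(y, fs = target_fs, record_id = rec$record_id,
             lead_name = rec$lead_name)
}

# smallest integer p/q with p/q == a/b (after scaling non-integer rates)
.rational_ratio <- function(a, b) {
  scale <- 1
  while ((abs(a * scale - round(a * scale)) > 1e-9 ||
          abs(b * scale - round(b * scale)) > 1e-9) && scale < 1e6)
    scale <- scale * 10
  p <- round(a * scale); q <- round(b * scale)
  g <- .gcd(p, q)
  c(p / g, q / g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Rescale annotations to a new sampling rate
#'
#' Companion to [resample_record()]: beat sample indices and episode
#' boundaries are multiplied by `target_fs / fs` and rounded, so annotations
#' stay aligned with the resampled signal.
#'
#' @param ann An [ecg_annotation()].
#' @param fs Original sampling rate (Hz).
#' @param target_fs New sampling rate (Hz).
#' @return An [ecg_annotation()] on the new time base.
#' @export
rescale_annotations <- function(ann, fs, target_fs) {
  r <- target_fs / fs
  beats <- if (nrow(ann$beats))
    data.frame(sample = round(ann$beats$sample * r),
               label = ann$beats$label) else NULL
  eps <- if (nrow(ann$episodes))
    data.frame(start = round(ann$episodes$start * r),
               end = round(ann$episodes$end * r),
               rhythm = ann$episodes$rhythm) else NULL
  ecg_annotation(beats = beats, episodes = eps)
}

#' Slice a record into consecutive analysis windows
#'
#' Cuts the record into non-overlapping windows of `window_s` seconds (the
#' pipeline's 5-minute analysis unit). A final partial window is kept — and
#' flagged via its `partial` attribute — when it is at least `min_partial_s`
#' seconds long; shorter tails are dropped (the dropped tail is available in
#' the `tail` attribute of the returned list, so window concatenation can
#' reconstruct the record).
#'
#' @param rec An [ecg_record()].
#' @param window_s Window length in seconds (default 300).
#' @param min_partial_s Minimum length for a retained partial window
#'   (default 60).
#' @return List of [ecg_record()] windows; each carries attributes
#'   `start_sample` (0-based offset into `rec`) and `partial`.
#' @export
slice_windows <- function(rec, window_s = 300, min_partial_s = 60) {
  if (window_s <= 0) stop("`window_s` must be positive")
  n <- length(rec$samples)
  wlen <- round(window_s * rec$fs)
  n_full <- n %/% wlen
  out <- vector("list", n_full)
  for (k in seq_len(n_full)) {
    i0 <- (k - 1L) * wlen
    w <- ecg_record(rec$samples[(i0 + 1L):(i0 + wlen)], fs = rec$fs,
                    record_id = sprintf("%s#w%d", rec$record_id, k),
                    lead_name = rec$lead_name)
    attr(w, "start_sample") <- i0
    attr(w, "partial") <- FALSE
    out[[k]] <- w
  }
  rem <- n - n_full * wlen
  tail_rec <- NULL
  if (rem > 0) {
    i0 <- n_full * wlen
    tail_samples <- rec$samples[(i0 + 1L):n]
    if (rem >= min_partial_s * rec$fs) {
      w <- ecg_record(tail_samples, fs = rec$fs,
                      record_id = sprintf("%s#w%d", rec$record_id, n_full + 1L),
                      lead_name = rec$lead_name)
      attr(w, "start_sample") <- i0
      attr(w, "partial") <- TRUE
      out[[n_full + 1L]] <- w
    } else {
      tail_rec <- ecg_record(tail_samples, fs = rec$fs,
                             record_id = sprintf("%s#tail", rec$record_id),
                             lead_name = rec$lead_name)
      attr(tail_rec, "start_sample") <- i0
    }
  }
  attr(out, "tail") <- tail_rec
  out
}
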