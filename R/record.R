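#' Construct a single-lead ECG record
#'
#' The basic container used throughout the package: a uniformly sampled
#' voltage series in millivolts with its sampling rate. All sample indices in
#' the package are 0-based so that index arithmetic against annotations and
#' episode boundaries is unambiguous.
#'
#' @param samples Numeric vector of voltages (mV). Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Character identifier for the record.
#' @param lead_name Character lead label (e.g. "MLII", "ECG1").
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 10, by = 1/200)), fs = 200)
#' rec
#' @export
ecg_record <- function(samples, fs, record_id = "record", lead_name = "ECG") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (length(samples) && any(!is.finite(samples)))
    stop("`samples` must be finite")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         record_id = as.character(record_id)[1L],
         lead_name = as.character(lead_name)[1L]),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record> %s [%s]: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead_name, length(x$samples), x$fs, dur))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Construct a beat/rhythm annotation set
#'
#' Holds beat marks (0-based sample index plus an AAMI-style class label) and
#' rhythm episodes as half-open `[start, end)` sample intervals. Beat labels
#' use the AAMI heart-beat classes: `N` (normal/bundle-branch/escape), `S`
#' (supraventricular ectopic), `V` (ventricular ectopic), `Q` (unclassifiable,
#' including paced). Rhythm names are `SINUS`, `AF`, `VF` or `OTHER`.
#'
#' @param beats Data frame with columns `sample` (0-based integer, strictly
#'   increasing) and `label` (one of N, S, V, Q), or `NULL` for none.
#' @param episodes Data frame with columns `start`, `end` (half-open 0-based
#'   sample interval, `start < end`) and `rhythm`, or `NULL` for none.
#' @return An object of class `ecg_annotation`.
#' @examples
#' ecg_annotation(beats = data.frame(sample = c(100, 300), label = c("N", "V")))
#' @export
ecg_annotation <- function(beats = NULL, episodes = NULL) {
  if (is.null(beats))
    beats <- data.frame(sample = integer(), label = character())
  if (is.null(episodes))
    episodes <- data.frame(start = numeric(), end = numeric(),
                           rhythm = character())
  beats <- data.frame(sample = as.numeric(beats$sample),
                      label = as.character(beats$label))
  episodes <- data.frame(start = as.numeric(episodes$start),
                         end = as.numeric(episodes$end),
                         rhythm = as.character(episodes$rhythm))
  if (nrow(beats) > 1L && any(diff(beats$sample) <= 0))
    stop("beat sample indices must be strictly increasing")
  if (nrow(episodes) && any(episodes$start >= episodes$end))
    stop("episode start must be < end (half-open [start, end))")
  for (rh in unique(episodes$rhythm)) {
    ep <- episodes[episodes$rhythm == rh, , drop = FALSE]
    if (nrow(ep) > 1L) {
      ep <- ep[order(ep$start), ]
      if (any(ep$start[-1L] < ep$end[-nrow(ep)]))
        stop(sprintf("overlapping '%s' episodes within one stream", rh))
    }
  }
  structure(list(beats = beats, episodes = episodes), class = "ecg_annotation")
}

#' @export
print.ecg_annotation <- function(x, ...) {
  cat(sprintf("<ecg_annotation> %d beats (%s), %d episodes (%s)\n",
              nrow(x$beats),
              paste(sprintf("%s:%d", names(table(x$beats$label)),
                            as.integer(table(x$beats$label))), collapse = " "),
              nrow(x$episodes),
              paste(unique(x$episodes$rhythm), collapse = " ")))
  invisible(x)
}

#' Construct a beat series
#'
#' Detected (or reference) beat locations on a record, with per-beat labels.
#' `beat_samples` are 0-based indices of the R-wave peaks; `labels` default to
#' `"unknown"` until a classifier assigns AAMI classes.
#'
#' @param beat_samples Strictly increasing 0-based sample indices.
#' @param fs Sampling rate (Hz) of the record the beats were detected on.
#' @param labels Per-beat character labels (`N`, `S`, `V`, `Q` or `unknown`).
#' @return Object of class `beat_series`.
#' @seealso [rr_intervals()], [detect_qrs()]
#' @export
beat_series <- function(beat_samples, fs, labels = NULL) {
  beat_samples <- as.numeric(beat_samples)
  if (length(beat_samples) > 1L && any(diff(beat_samples) <= 0))
    stop("`beat_samples` must be strictly increasing")
  if (is.null(labels)) labels <- rep("unknown", length(beat_samples))
  if (length(labels) != length(beat_samples))
    stop("`labels` must match `beat_samples` in length")
  structure(list(beat_samples = beat_samples, fs = as.numeric(fs),
                 labels = as.character(labels)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats @ %g Hz", length(x$beat_samples), x$fs))
  if (length(x$beat_samples) > 1L) {
    rr <- rr_intervals(x)
    cat(sprintf(", mean RR %.3f s (%.0f bpm)", mean(rr), 60 / mean(rr)))
  }
  cat("\n")
  invisible(x)
}

#' RR intervals of a beat series
#'
#' Successive differences of beat times in seconds. Empty when fewer than two
#' beats are present.
#'
#' @param beats A [beat_series()].
#' @return Numeric vector of RR intervals (s), length `n_beats - 1`.
#' @examples
#' rr_intervals(beat_series(c(200, 400, 600), fs = 200))  # 1.0 1.0
#' @export
rr_intervals <- function(beats) {
  if (length(beats$beat_samples) < 2L) return(numeric())
  diff(beats$beat_samples) / beats$fs
}
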