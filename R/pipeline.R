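# Integrated record-level flow: resample to 200 Hz, slice 5-minute
# windows, detect beats, classify VPC, decide AF per window from the
# corrected RR series, optionally classify APC with a trained perceptron,
# then classify 2-s segments for VF on the raw signal and assemble
# rhythm episodes. AF and VF are computed on disjoint representations
# (RR series vs raw segments); an optional override clears ventricular
# beat labels inside detected VF episodes, since oscillatory VF waveform
# is otherwise prone to being picked up as wide ectopic beats.

#' Full pipeline configuration
#'
#' Nests every stage's tunables: `fs` (working rate, 200 Hz), `window_s`
#' (analysis window, 300 s), `min_partial_s` (shortest retained partial
#' window, 60 s), `qrs` ([qrs_config()]), `vpc` (width/prematurity factors),
#' `af` ([af_config()]), `vf` ([vf_config()]), `vf_override` (clear V labels
#' inside VF episodes, default TRUE), `ec57` (beat-match tolerance and
#' record exclusion list).
#'
#' @return Nested named list.
#' @export
ecg_config <- function() {
  list(fs = 200, window_s = 300, min_partial_s = 60,
       qrs = qrs_config(),
       vpc = list(width_factor = 1.5, prematurity_factor = 0.85,
                  median_window = 50L),
       af = af_config(),
       vf = vf_config(),
       vf_override = TRUE,
       ec57 = list(tolerance_s = 0.15,
                   excluded_records = c("102", "104", "107", "217",
                                        "2202", "8205")))
}

#' Run the integrated arrhythmia pipeline on one record
#'
#' Stage order is fixed: resampling, 5-minute windowing, QRS detection,
#' feature extraction, VPC rule, per-window AF decision on the
#' VPC-corrected RR series, APC classification (when a trained model is
#' supplied; V labels are never overwritten), then 2-s VF segmentation of
#' the raw windows and episode assembly. With `vf_override` enabled,
#' beats inside detected VF episodes have ventricular labels cleared to
#' `Q` and are flagged, so oscillatory VF waveform does not surface as
#' ectopic beats.
#'
#' @param rec An [ecg_record()] at any sampling rate.
#' @param config See [ecg_config()].
#' @param model Optional trained `mlp_model` enabling the APC stage.
#' @return Object of class `pipeline_result`: `record_id`, `beats`
#'   (a [beat_series()] on the 200 Hz time base with final labels and a
#'   `vf_override` flag vector), `episodes` (AF/VF data frame), `af_windows`
#'   (per-window decisions), `vf_segments` (per-segment ratio trace),
#'   `config`.
#' @export
run_pipeline <- function(rec, config = ecg_config(), model = NULL) {
  rec200 <- resample_record(rec, config$fs)
  windows <- slice_windows(rec200, config$window_s, config$min_partial_s)

  all_samp <- numeric(); all_lab <- character()
  af_dec <- list()
  wb <- data.frame(start = numeric(), end = numeric())
  for (k in seq_along(windows)) {
    w <- windows[[k]]
    off <- attr(w, "start_sample")
    beats <- detect_qrs(w, config$qrs)
    feats <- extract_beat_features(w, beats)
    beats <- classify_vpc(feats, beats,
                          width_factor = config$vpc$width_factor,
                          prematurity_factor = config$vpc$prematurity_factor,
                          median_window = config$vpc$median_window)
    af_dec[[k]] <- detect_af_window(beats, config$af, window_id = k)
    if (!is.null(model))
      beats <- classify_apc(model, feats, beats)
    all_samp <- c(all_samp, beats$beat_samples + off)
    all_lab <- c(all_lab, beats$labels)
    wb <- rbind(wb, data.frame(start = off,
                               end = off + length(w$samples)))
  }

  eps_af <- af_episodes(af_dec, wb)
  vf <- detect_vf(rec200, config$vf)
  episodes <- rbind(eps_af, vf$episodes)

  override <- rep(FALSE, length(all_samp))
  if (isTRUE(config$vf_override) && nrow(vf$episodes)) {
    for (j in seq_len(nrow(vf$episodes))) {
      inside <- all_samp >= vf$episodes$start[j] &
        all_samp < vf$episodes$end[j]
      override <- override | inside
    }
    all_lab[override & all_lab == "V"] <- "Q"
  }

  beats_out <- beat_series(all_samp, fs = config$fs, labels = all_lab)
  beats_out$vf_override <- override

  af_tab <- data.frame(
    window_id = vapply(af_dec, `[[`, numeric(1L), "window_id"),
    start = wb$start, end = wb$end,
    n_beats = vapply(af_dec, `[[`, numeric(1L), "n_beats"),
    sampen = vapply(af_dec, `[[`, numeric(1L), "sampen"),
    is_af = vapply(af_dec, function(d)
      if (is.na(d$is_af)) NA else d$is_af, logical(1L)))

  structure(list(record_id = rec$record_id, beats = beats_out,
                 episodes = episodes, af_windows = af_tab,
                 vf_segments = vf$segments, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d beats (%s); %d episode(s)%s\n",
              x$record_id, length(x$beats$beat_samples),
              paste(sprintf("%s:%d", names(table(x$beats$labels)),
                            as.integer(table(x$beats$labels))),
                    collapse = " "),
              nrow(x$episodes),
              if (nrow(x$episodes))
                paste0(" [", paste(x$episodes$rhythm, collapse = " "), "]")
              else ""))
  invisible(x)
}

#' Annotation view of a pipeline result
#'
#' Converts the detected beats and episodes to an [ecg_annotation()], ready
#' for EC57 scoring against a reference or for serialization.
#'
#' @param result A `pipeline_result`.
#' @return An [ecg_annotation()].
#' @export
as_annotation <- function(result) {
  eps <- result$episodes
  ecg_annotation(
    beats = if (length(result$beats$beat_samples))
      data.frame(sample = result$beats$beat_samples,
                 label = result$beats$labels) else NULL,
    episodes = if (nrow(eps)) eps else NULL)
}

#' Score a pipeline result against a reference annotation
#'
#' Convenience wrapper producing, for one record, the beat-level matches
#' for classes S and V and the episode/duration statistics for AF and VF.
#'
#' @param ref Reference [ecg_annotation()] (on the pipeline's 200 Hz base).
#' @param result A `pipeline_result` (or an [ecg_annotation()]).
#' @param config See [ecg_config()] (supplies the match tolerance).
#' @return List with `beat` (named list of `beat_match` for S, V) and
#'   `episode` (named list of `episode_stats` for AF, VF).
#' @export
evaluate_record <- function(ref, result, config = ecg_config()) {
  test <- if (inherits(result, "pipeline_result")) as_annotation(result)
          else result
  list(
    beat = list(
      S = match_beats(ref, test, "S", fs = config$fs,
                      tolerance_s = config$ec57$tolerance_s),
      V = match_beats(ref, test, "V", fs = config$fs,
                      tolerance_s = config$ec57$tolerance_s)),
    episode = list(
      AF = episode_duration_stats(ref$episodes, test$episodes, "AF"),
      VF = episode_duration_stats(ref$episodes, test$episodes, "VF")))
}
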