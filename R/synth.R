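# Seeded synthetic single-lead ECG with exact ground truth, standing in
# for patient-simulator hardware and clinical databases in tests and
# calibration. Beats are sums of Gaussian P-QRS-T waves; atrial
# fibrillation draws RR intervals i.i.d. from a configurable law with
# suppressed P waves and fibrillatory baseline wavelets; ventricular
# fibrillation is an amplitude- and frequency-modulated oscillation with
# no discrete beats. Ground-truth beat marks coincide exactly with the
# generated R-peak samples.

#' One segment of a rhythm plan
#'
#' @param rhythm `"SINUS"`, `"AF"` or `"VF"`.
#' @param duration_s Segment duration in seconds (> 0).
#' @return One-row data frame usable in `rhythm_plan`.
#' @export
plan_segment <- function(rhythm, duration_s) {
  stopifnot(rhythm %in% c("SINUS", "AF", "VF"), duration_s > 0)
  data.frame(rhythm = rhythm, duration_s = duration_s)
}

#' Synthetic-record configuration
#'
#' Defaults describe a plausible resting adult: 70 bpm sinus rhythm with
#' 30 ms RR jitter; atrial premature complexes arrive 30\% early with an
#' altered P wave; ventricular premature complexes arrive 40\% early, wide,
#' without P and with a compensatory pause; AF RR intervals are i.i.d.
#' uniform on 0.35–1.0 s; VF oscillates in the 3–5 Hz band with a
#' mean-reverting instantaneous frequency and ±30\% amplitude modulation.
#'
#' @param fs Sampling rate (Hz, default 200).
#' @param rhythm_plan Data frame of [plan_segment()] rows, played in order.
#' @param sinus_rate_bpm Mean sinus rate (default 70).
#' @param rr_jitter_sd SD of sinus RR jitter in seconds (default 0.03).
#' @param apc_rate,vpc_rate Ectopic events per minute during sinus segments
#'   (default 0).
#' @param af_rr_law List `(name, ...)`: `"uniform"` with `min`, `max`
#'   (default 0.35–1.0 s) or `"lognormal"` with `meanlog`, `sdlog`.
#' @param vf_freq_band VF instantaneous-frequency band in Hz (default
#'   c(3, 5); must lie within (0.5, 10]).
#' @param noise_snr_db Additive white-noise SNR in dB, or `NULL` for a
#'   clean record.
#' @param baseline_wander Add a < 0.5 Hz baseline drift component.
#' @param mains_hz Add a mains interference tone at this frequency
#'   (e.g. 50 or 60), or `NULL`.
#' @param seed Integer RNG seed; the whole record is a deterministic
#'   function of the configuration.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(fs = 200,
                         rhythm_plan = plan_segment("SINUS", 300),
                         sinus_rate_bpm = 70, rr_jitter_sd = 0.03,
                         apc_rate = 0, vpc_rate = 0,
                         af_rr_law = list(name = "uniform", min = 0.35,
                                          max = 1.0),
                         vf_freq_band = c(3, 5),
                         noise_snr_db = NULL, baseline_wander = FALSE,
                         mains_hz = NULL, seed = 1L) {
  stopifnot(all(rhythm_plan$duration_s > 0),
            vf_freq_band[1L] > 0.5, vf_freq_band[2L] <= 10,
            vf_freq_band[1L] < vf_freq_band[2L])
  structure(list(fs = fs, rhythm_plan = rhythm_plan,
                 sinus_rate_bpm = sinus_rate_bpm,
                 rr_jitter_sd = rr_jitter_sd,
                 apc_rate = apc_rate, vpc_rate = vpc_rate,
                 af_rr_law = af_rr_law, vf_freq_band = vf_freq_band,
                 noise_snr_db = noise_snr_db,
                 baseline_wander = baseline_wander, mains_hz = mains_hz,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian wave parameters (offset from R in s, amplitude in mV, SD in s)
.beat_waves <- function(type) {
  switch(type,
    normal = list(P = c(-0.17, 0.12, 0.020), Q = c(-0.026, -0.08, 0.009),
                  R = c(0, 1.0, 0.011), S = c(0.026, -0.14, 0.009),
                  T = c(0.23, 0.28, 0.050)),
    apc = list(P = c(-0.12, 0.16, 0.012), Q = c(-0.026, -0.08, 0.009),
               R = c(0, 1.0, 0.011), S = c(0.026, -0.14, 0.009),
               T = c(0.23, 0.28, 0.050)),
    af = list(Q = c(-0.026, -0.08, 0.009), R = c(0, 1.0, 0.011),
              S = c(0.026, -0.14, 0.009), T = c(0.23, 0.28, 0.050)),
    vpc = list(R = c(0, 1.3, 0.024), S = c(0.050, -0.35, 0.030),
               T = c(0.30, -0.30, 0.070)))
}

.add_gauss <- function(sig, fs, center_s, amp, sd_s) {
  n <- length(sig)
  i0 <- max(1L, floor((center_s - 5 * sd_s) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + 5 * sd_s) * fs) + 1L)
  if (i0 > i1) return(sig)
  t <- (i0:i1 - 1) / fs
  sig[i0:i1] <- sig[i0:i1] + amp * exp(-(t - center_s)^2 / (2 * sd_s^2))
  sig
}

.draw_af_rr <- function(law, n) {
  switch(law$name,
         uniform = stats::runif(n, law$min, law$max),
         lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
         stop("unknown AF RR law: ", law$name))
}

#' Generate a synthetic ECG record with ground truth
#'
#' Plays the configured rhythm plan and returns the signal plus an
#' annotation whose beat marks are exactly the generated R-peak sample
#' indices and whose episodes are the plan segments. Sinus segments insert
#' APC (`S`) and VPC (`V`) events at the configured rates; AF segments
#' carry `N`-labeled beats on irregular RR; VF segments contain no
#' annotated beats.
#'
#' @param config A [synth_config()].
#' @return List with `record` ([ecg_record()]), `annotation`
#'   ([ecg_annotation()]) and `beat_types` (per-beat generator type:
#'   normal/apc/vpc/af, with the nominal QRS width in the `qrs_width`
#'   attribute).
#' @export
synth_record <- function(config) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  fs <- config$fs
  plan <- config$rhythm_plan
  total_s <- sum(plan$duration_s)
  n <- round(total_s * fs)
  sig <- numeric(n)
  beat_t <- numeric(); beat_lab <- character(); beat_type <- character()
  eps <- data.frame(start = numeric(), end = numeric(), rhythm = character())

  mean_rr <- 60 / config$sinus_rate_bpm
  t0 <- 0
  for (k in seq_len(nrow(plan))) {
    t1 <- t0 + plan$duration_s[k]
    rhythm <- plan$rhythm[k]
    eps <- rbind(eps, data.frame(start = round(t0 * fs), end = round(t1 * fs),
                                 rhythm = rhythm))
    if (rhythm == "SINUS") {
      if (mean_rr * 1.1 > plan$duration_s[k])
        stop("infeasible plan: segment too short for one beat")
      t <- t0 + mean_rr / 2
      pending_compensation <- FALSE
      while (t < t1 - 0.1) {
        beat_t <- c(beat_t, t)
        # decide the next event
        p_apc <- config$apc_rate * mean_rr / 60
        p_vpc <- config$vpc_rate * mean_rr / 60
        u <- stats::runif(1)
        if (u < p_vpc && t + 0.60 * mean_rr < t1 - 0.1) {
          beat_lab <- c(beat_lab, "N"); beat_type <- c(beat_type, "normal")
          t <- t + 0.60 * mean_rr
          beat_t <- c(beat_t, t)
          beat_lab <- c(beat_lab, "V"); beat_type <- c(beat_type, "vpc")
          # compensatory pause: coupling + pause = 2 sinus cycles
          t <- t + (2 - 0.60) * mean_rr
        } else if (u < p_vpc + p_apc && t + 0.70 * mean_rr < t1 - 0.1) {
          beat_lab <- c(beat_lab, "N"); beat_type <- c(beat_type, "normal")
          t <- t + 0.70 * mean_rr
          beat_t <- c(beat_t, t)
          beat_lab <- c(beat_lab, "S"); beat_type <- c(beat_type, "apc")
          t <- t + mean_rr + stats::rnorm(1, 0, config$rr_jitter_sd)
        } else {
          beat_lab <- c(beat_lab, "N"); beat_type <- c(beat_type, "normal")
          t <- t + max(0.3, mean_rr + stats::rnorm(1, 0, config$rr_jitter_sd))
        }
      }
    } else if (rhythm == "AF") {
      t <- t0 + 0.4
      while (TRUE) {
        rr <- .draw_af_rr(config$af_rr_law, 1L)
        rr <- max(0.3, rr)
        if (t >= t1 - 0.1) break
        beat_t <- c(beat_t, t)
        beat_lab <- c(beat_lab, "N"); beat_type <- c(beat_type, "af")
        t <- t + rr
      }
      # fibrillatory baseline wavelets (4-9 Hz)
      idx <- (floor(t0 * fs) + 1L):min(n, round(t1 * fs))
      tt <- (idx - 1) / fs
      for (w in seq_len(6L)) {
        fw <- stats::runif(1, 4, 9)
        aw <- stats::runif(1, 0.02, 0.06)
        sig[idx] <- sig[idx] + aw * sin(2 * pi * fw * tt + stats::runif(1, 0, 2 * pi))
      }
    } else if (rhythm == "VF") {
      idx <- (floor(t0 * fs) + 1L):min(n, round(t1 * fs))
      m <- length(idx)
      band <- config$vf_freq_band
      mu <- mean(band); theta <- 2; sigma <- 1.0; dt <- 1 / fs
      f <- numeric(m); f[1L] <- mu
      ev <- stats::rnorm(m)
      for (i in 2:m)
        f[i] <- min(band[2L], max(band[1L],
          f[i - 1L] + theta * (mu - f[i - 1L]) * dt + sigma * sqrt(dt) * ev[i]))
      phase <- 2 * pi * cumsum(f) * dt
      tt <- (seq_len(m) - 1) * dt
      amp <- 1.0 * (1 + 0.3 * sin(2 * pi * 0.4 * tt + stats::runif(1, 0, 2 * pi)))
      sig[idx] <- sig[idx] + amp * sin(phase)
    }
    t0 <- t1
  }

  if (!length(beat_t) && any(plan$rhythm %in% c("SINUS", "AF")))
    stop("infeasible plan: rate x duration yields no beats")

  # render beats on the exact sample grid so truth marks match R peaks
  beat_samp <- round(beat_t * fs)
  beat_t_snap <- beat_samp / fs
  qrs_width <- numeric(length(beat_t))
  for (b in seq_along(beat_t_snap)) {
    waves <- .beat_waves(beat_type[b])
    for (wv in waves)
      sig <- .add_gauss(sig, fs, beat_t_snap[b] + wv[1L], wv[2L], wv[3L])
    span <- range(vapply(waves[setdiff(names(waves), c("P", "T"))],
                         function(w) w[1L], numeric(1L)))
    sds <- vapply(waves[setdiff(names(waves), c("P", "T"))],
                  function(w) w[3L], numeric(1L))
    qrs_width[b] <- diff(span) + 2 * 2.146 * max(sds)
  }

  if (config$baseline_wander)
    sig <- sig + 0.15 * sin(2 * pi * 0.25 * (seq_len(n) - 1) / fs +
                              stats::runif(1, 0, 2 * pi))
  if (!is.null(config$mains_hz))
    sig <- sig + 0.05 * sin(2 * pi * config$mains_hz * (seq_len(n) - 1) / fs)
  if (!is.null(config$noise_snr_db)) {
    p_sig <- mean(sig^2)
    sd_n <- sqrt(p_sig / 10^(config$noise_snr_db / 10))
    sig <- sig + stats::rnorm(n, 0, sd_n)
  }

  keep <- !duplicated(beat_samp)
  ann <- ecg_annotation(
    beats = if (length(beat_samp))
      data.frame(sample = beat_samp[keep], label = beat_lab[keep]) else NULL,
    episodes = eps)
  types <- beat_type[keep]
  attr(types, "qrs_width") <- qrs_width[keep]
  list(record = ecg_record(sig, fs = fs,
                           record_id = sprintf("synth-%d", config$seed)),
       annotation = ann, beat_types = types)
}

#' Generate a corpus of synthetic records
#'
#' Per-record seeds are derived deterministically from the master seed, so
#' the corpus is reproducible and its records mutually distinct.
#'
#' @param n_records Number of records (>= 1).
#' @param template_configs A single [synth_config()] or a list of them,
#'   recycled over records.
#' @param seed Master seed.
#' @return List of `synth_record()` results; the `summary` attribute
#'   holds per-class beat counts and per-rhythm episode counts.
#' @export
synth_corpus <- function(n_records, template_configs, seed = 1L) {
  stopifnot(n_records >= 1L)
  if (inherits(template_configs, "synth_config"))
    template_configs <- list(template_configs)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, n_records)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  out <- vector("list", n_records)
  for (k in seq_len(n_records)) {
    cfg <- template_configs[[(k - 1L) %% length(template_configs) + 1L]]
    cfg$seed <- seeds[k]
    out[[k]] <- synth_record(cfg)
    out[[k]]$record$record_id <- sprintf("synth-%02d", k)
  }
  labs <- unlist(lapply(out, function(r) r$annotation$beats$label))
  rhys <- unlist(lapply(out, function(r) r$annotation$episodes$rhythm))
  attr(out, "summary") <- list(beat_counts = table(labs),
                               episode_counts = table(rhys))
  out
}

#' Generate one window of beats directly from an RR law
#'
#' Cheaper companion to [synth_record()] for RR-level experiments (AF
#' threshold calibration, entropy separation): beat times are accumulated
#' directly from the sinus or AF inter-beat law without waveform synthesis.
#'
#' @param rhythm `"SINUS"` or `"AF"`.
#' @param duration_s Window length in seconds (default 300).
#' @param fs Sampling rate for the sample indices (default 200).
#' @param sinus_rate_bpm,rr_jitter_sd Sinus law parameters.
#' @param af_rr_law AF RR law, as in [synth_config()].
#' @param seed RNG seed.
#' @return A [beat_series()] labeled `N`.
#' @export
synth_beats <- function(rhythm = c("SINUS", "AF"), duration_s = 300,
                        fs = 200, sinus_rate_bpm = 70, rr_jitter_sd = 0.03,
                        af_rr_law = list(name = "uniform", min = 0.35,
                                         max = 1.0),
                        seed = 1L) {
  rhythm <- match.arg(rhythm)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  t <- 0.5; times <- numeric()
  mean_rr <- 60 / sinus_rate_bpm
  while (t < duration_s) {
    times <- c(times, t)
    rr <- if (rhythm == "SINUS")
      max(0.3, mean_rr + stats::rnorm(1, 0, rr_jitter_sd))
    else max(0.3, .draw_af_rr(af_rr_law, 1L))
    t <- t + rr
  }
  beat_series(round(times * fs), fs = fs, labels = rep("N", length(times)))
}
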