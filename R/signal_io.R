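# Reading and writing of single-lead ECG records and annotations.
#
# Supported on disk:
#   * WFDB header/signal pairs (.hea + .dat, storage formats 16 and 212)
#   * MIT-style binary annotation files (.atr and friends)
#   * two-column CSV (time_s, mV)
#   * a JSON annotation dialect {beats:[{sample,label}], episodes:[...]}
#
# Sample indices are 0-based everywhere; voltages are in mV.

# standard MIT annotation code table (code -> symbol)
.mit_codes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "x",
  "33" = "(", "34" = ")", "35" = "e", "36" = "n")
.mit_symbols <- stats::setNames(as.integer(names(.mit_codes)),
                                unname(.mit_codes))

# AAMI class map for MIT beat symbols; anything else becomes Q
.aami_map <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
               A = "S", a = "S", J = "S", S = "S",
               V = "V", E = "V",
               "/" = "Q", f = "Q", Q = "Q")

.rhythm_map <- function(aux) {
  aux <- sub("^\\(", "", aux)
  switch(aux,
         "AFIB" = "AF", "AFL" = "AF",
         "VF" = "VF", "VFL" = "VF", "VFIB" = "VF",
         "N" = "SINUS", "NSR" = "SINUS", "SR" = "SINUS",
         "OTHER")
}

#' Read an ECG record from disk
#'
#' Reads either a WFDB record (pass the `.hea` header path; signal storage
#' formats 16 and 212 are supported) or a two-column CSV of
#' `(time_s, amplitude_mV)` rows, in which case the sampling rate is inferred
#' from the median time step. WFDB ADC units are converted to mV using the
#' gain and baseline declared in the header.
#'
#' @param path Path to a `.hea` header or a `.csv` file.
#' @return An [ecg_record()].
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(.read_csv_record(path))
  .read_wfdb_record(path)
}

.read_csv_record <- function(path) {
  d <- utils::read.csv(path, header = FALSE,
                       col.names = c("time_s", "mV"),
                       colClasses = "numeric")
  if (nrow(d) >= 2L) {
    fs <- 1 / stats::median(diff(d$time_s))
  } else {
    fs <- 200
  }
  ecg_record(d$mV, fs = fs,
             record_id = sub("\\.csv$", "", basename(path), ignore.case = TRUE))
}

.parse_hea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rec_name <- sub("/.*$", "", top[1L])
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  nsamp <- if (length(top) >= 4L) as.numeric(top[4L]) else NA_real_
  if (nsig < 1L) stop("header declares no signals: ", path)
  sig <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]  # first signal only
  file_name <- sig[1L]
  fmt <- as.integer(sub("[x:+].*$", "", sig[2L]))
  gain <- 200; baseline <- NA_real_; units <- "mV"
  if (length(sig) >= 3L) {
    gspec <- sig[3L]
    if (grepl("/", gspec)) { units <- sub("^.*/", "", gspec); gspec <- sub("/.*$", "", gspec) }
    if (grepl("\\(", gspec)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec))
      gspec <- sub("\\(.*$", "", gspec)
    }
    gain <- as.numeric(gspec)
    if (!is.finite(gain) || gain == 0) gain <- 200
  }
  adc_zero <- if (length(sig) >= 5L) as.numeric(sig[5L]) else 0
  if (!is.finite(baseline)) baseline <- adc_zero
  desc <- if (length(sig) >= 9L) paste(sig[9:length(sig)], collapse = " ") else "ECG"
  list(record = rec_name, nsig = nsig, fs = fs, nsamp = nsamp,
       file = file_name, fmt = fmt, gain = gain, baseline = baseline,
       units = units, desc = desc)
}

.read_wfdb_record <- function(hea_path) {
  h <- .parse_hea(hea_path)
  dat_path <- file.path(dirname(hea_path), h$file)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  raw_bytes <- readBin(dat_path, what = "raw", n = file.size(dat_path))
  if (h$fmt == 16L) {
    adu <- readBin(raw_bytes, what = "integer", size = 2L, signed = TRUE,
                   endian = "little", n = length(raw_bytes) %/% 2L)
    if (h$nsig > 1L) adu <- adu[seq(1L, length(adu), by = h$nsig)]
  } else if (h$fmt == 212L) {
    adu <- .decode_212(raw_bytes)
    if (h$nsig > 1L) adu <- adu[seq(1L, length(adu), by = h$nsig)]
  } else {
    stop("unsupported WFDB signal storage format: ", h$fmt)
  }
  if (is.finite(h$nsamp) && h$nsamp > 0) adu <- adu[seq_len(min(length(adu), h$nsamp))]
  ecg_record((adu - h$baseline) / h$gain, fs = h$fs,
             record_id = h$record, lead_name = h$desc)
}

.decode_212 <- function(bytes) {
  n3 <- (length(bytes) %/% 3L) * 3L
  b <- as.integer(bytes[seq_len(n3)])
  b0 <- b[seq(1L, n3, by = 3L)]
  b1 <- b[seq(2L, n3, by = 3L)]
  b2 <- b[seq(3L, n3, by = 3L)]
  s1 <- bitwAnd(b1, 0x0FL) * 256L + b0
  s2 <- bitwAnd(b1, 0xF0L) * 16L + b2
  s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
  s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
  as.vector(rbind(s1, s2))
}

.encode_212 <- function(adu) {
  if (length(adu) %% 2L) adu <- c(adu, 0L)  # pad to sample pair
  adu <- as.integer(adu)
  if (any(adu < -2048L | adu > 2047L))
    stop("sample out of 12-bit range for format 212")
  adu <- ifelse(adu < 0L, adu + 4096L, adu)
  s1 <- adu[seq(1L, length(adu), by = 2L)]
  s2 <- adu[seq(2L, length(adu), by = 2L)]
  b0 <- bitwAnd(s1, 0xFFL)
  b1 <- bitwAnd(s1 %/% 256L, 0x0FL) + bitwAnd(s2 %/% 256L, 0x0FL) * 16L
  b2 <- bitwAnd(s2, 0xFFL)
  as.raw(as.vector(rbind(b0, b1, b2)))
}

#' Write an ECG record as a WFDB header/signal pair
#'
#' Digitizes the mV series with the given gain and baseline and writes a
#' `.hea` header plus `.dat` signal file in storage format 16 (little-endian
#' 16-bit) or 212 (packed 12-bit pairs).
#'
#' @param rec An [ecg_record()].
#' @param path_prefix Output path without extension; `.hea` and `.dat` are
#'   appended.
#' @param fmt Storage format, 16 (default) or 212.
#' @param gain ADC units per mV (default 200).
#' @param baseline ADC value corresponding to 0 mV (default 0).
#' @return The header path, invisibly.
#' @export
write_record_wfdb <- function(rec, path_prefix, fmt = 16L, gain = 200,
                              baseline = 0) {
  fmt <- as.integer(fmt)
  if (!fmt %in% c(16L, 212L)) stop("fmt must be 16 or 212")
  adu <- as.integer(round(rec$samples * gain + baseline))
  dat <- paste0(basename(path_prefix), ".dat")
  hea <- paste0(path_prefix, ".hea")
  hdr <- c(sprintf("%s 1 %g %d", basename(path_prefix), rec$fs, length(adu)),
           sprintf("%s %d %g(%g)/mV 12 0 %d 0 0 %s",
                   dat, fmt, gain, baseline,
                   if (length(adu)) adu[1L] else 0L, rec$lead_name))
  writeLines(hdr, hea)
  con <- file(paste0(path_prefix, ".dat"), "wb")
  on.exit(close(con))
  if (fmt == 16L) {
    writeBin(adu, con, size = 2L, endian = "little")
  } else {
    writeBin(.encode_212(adu), con)
  }
  invisible(hea)
}

#' Read beat and rhythm annotations
#'
#' Reads either a MIT-style binary annotation file or the package's JSON
#' annotation dialect (dispatch on the `.json` extension). MIT beat symbols
#' are mapped to AAMI classes (`N,L,R,e,j -> N`; `A,a,J,S -> S`; `V,E -> V`;
#' everything else, including paced, `-> Q`); rhythm change marks (`(AFIB`,
#' `(VFL`, `(N`, ...) are paired into closed half-open episodes. A rhythm
#' still open at the end of the stream is closed at `n_samples` (or at the
#' last annotated sample + 1 when `n_samples` is `NULL`).
#'
#' @param path Annotation file path.
#' @param n_samples Optional record length used to close a dangling rhythm.
#' @return An [ecg_annotation()].
#' @export
read_annotations <- function(path, n_samples = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(read_annotations_json(path))
  .read_mit_annotations(path, n_samples)
}

.read_mit_annotations <- function(path, n_samples = NULL) {
  bytes <- readBin(path, what = "raw", n = file.size(path))
  n <- length(bytes)
  i <- 1L; t <- 0
  samp <- numeric(); code <- integer(); auxs <- character()
  pending_skip <- 0
  while (i + 1L <= n) {
    lo <- as.integer(bytes[i]); hi <- as.integer(bytes[i + 1L]); i <- i + 2L
    a <- hi %/% 4L              # 6-bit annotation code
    dt <- bitwAnd(hi, 3L) * 256L + lo  # 10-bit time delta
    if (a == 0L && dt == 0L) break     # EOF
    if (a == 59L) {             # SKIP: 4-byte long interval follows
      if (i + 3L > n) break
      hi16 <- as.integer(bytes[i]) + as.integer(bytes[i + 1L]) * 256L
      lo16 <- as.integer(bytes[i + 2L]) + as.integer(bytes[i + 3L]) * 256L
      iv <- hi16 * 65536 + lo16
      if (iv >= 2^31) iv <- iv - 2^32
      pending_skip <- pending_skip + iv
      i <- i + 4L
    } else if (a == 63L) {      # AUX: dt bytes of text, padded to even
      len <- dt
      ab <- bytes[seq.int(i, length.out = len)]
      aux <- trimws(rawToChar(ab[ab != as.raw(0L)]))
      if (length(code)) auxs[length(code)] <- aux
      i <- i + len + (len %% 2L)
    } else if (a %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: ignored
    } else {
      t <- t + pending_skip + dt
      pending_skip <- 0
      samp <- c(samp, t); code <- c(code, a); auxs <- c(auxs, NA_character_)
    }
  }
  .annotations_from_events(samp, code, auxs, n_samples)
}

.annotations_from_events <- function(samp, code, auxs, n_samples) {
  sym <- .mit_codes[as.character(code)]
  beat_codes <- c(1:13, 25L, 30L, 31L, 35L, 36L, 38L)
  is_beat <- code %in% beat_codes
  beats <- NULL
  if (any(is_beat)) {
    lab <- .aami_map[sym[is_beat]]
    if (anyNA(lab)) {
      warning("unknown beat symbol(s) mapped to Q: codes ",
              paste(unique(code[is_beat][is.na(lab)]), collapse = ","))
      lab[is.na(lab)] <- "Q"
    }
    beats <- data.frame(sample = samp[is_beat], label = unname(lab))
  }
  # rhythm events -> closed episodes
  is_rh <- code == 28L & !is.na(auxs)
  episodes <- NULL
  if (any(is_rh)) {
    rs <- samp[is_rh]; rl <- vapply(auxs[is_rh], .rhythm_map, character(1L))
    end_at <- if (!is.null(n_samples)) n_samples else max(samp) + 1
    st <- rs; en <- c(rs[-1L], end_at); rh <- rl
    keep <- en > st
    episodes <- data.frame(start = st[keep], end = en[keep], rhythm = rh[keep])
  }
  ecg_annotation(beats = beats, episodes = episodes)
}

#' Write annotations as a MIT-style binary file
#'
#' Serializes beats (AAMI labels mapped back to the canonical MIT symbols
#' `N`, `A`, `V`, `Q`) and rhythm episodes (as `+` marks with `(AFIB`/`(VFL`/
#' `(N` aux strings) in the standard 2-byte-word annotation format, with SKIP
#' words for inter-annotation gaps exceeding 1023 samples.
#'
#' @param ann An [ecg_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_mit <- function(ann, path) {
  ev_s <- ann$beats$sample
  ev_c <- .mit_symbols[c(N = "N", S = "A", V = "V", Q = "Q",
                         unknown = "N")[ann$beats$label]]
  ev_a <- rep(NA_character_, length(ev_s))
  if (nrow(ann$episodes)) {
    aux_of <- c(AF = "(AFIB", VF = "(VFL", SINUS = "(N", OTHER = "(OTHER")
    ep <- ann$episodes[order(ann$episodes$start), , drop = FALSE]
    for (k in seq_len(nrow(ep))) {
      ev_s <- c(ev_s, ep$start[k], ep$end[k])
      ev_c <- c(ev_c, .mit_symbols[["+"]], .mit_symbols[["+"]])
      ev_a <- c(ev_a, aux_of[[ep$rhythm[k]]], "(N")
    }
  }
  o <- order(ev_s)
  ev_s <- ev_s[o]; ev_c <- ev_c[o]; ev_a <- ev_a[o]
  # drop duplicate rhythm marks at identical samples (episode end == next start)
  con <- file(path, "wb"); on.exit(close(con))
  t_prev <- 0
  wword <- function(code, dt) {
    w <- code * 1024L + as.integer(dt)
    writeBin(as.raw(c(bitwAnd(w, 0xFFL), w %/% 256L)), con)
  }
  for (k in seq_along(ev_s)) {
    dt <- ev_s[k] - t_prev
    if (dt > 1023) {
      # SKIP word, then the long interval: high 16 bits first, each LE
      wword(59L, 0L)
      iv <- as.integer(dt)
      hi16 <- iv %/% 65536L; lo16 <- iv %% 65536L
      writeBin(as.raw(c(hi16 %% 256L, hi16 %/% 256L,
                        lo16 %% 256L, lo16 %/% 256L)), con)
      dt <- 0L
    }
    wword(as.integer(ev_c[k]), dt)
    t_prev <- ev_s[k]
    if (!is.na(ev_a[k])) {
      aux <- charToRaw(ev_a[k])
      wword(63L, length(aux))
      if (length(aux) %% 2L) aux <- c(aux, as.raw(0L))
      writeBin(aux, con)
    }
  }
  wword(0L, 0L)  # EOF
  invisible(path)
}

#' @rdname read_annotations
#' @export
read_annotations_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beats <- if (!is.null(j$beats) && length(j$beats))
    data.frame(sample = j$beats$sample, label = j$beats$label) else NULL
  eps <- if (!is.null(j$episodes) && length(j$episodes))
    data.frame(start = j$episodes$start, end = j$episodes$end,
               rhythm = j$episodes$rhythm) else NULL
  ecg_annotation(beats = beats, episodes = eps)
}

#' Write annotations in the JSON dialect
#'
#' The dialect is `{"beats":[{"sample":..,"label":..}],
#' "episodes":[{"start":..,"end":..,"rhythm":..}]}` with 0-based samples and
#' half-open episodes; the round trip through [read_annotations_json()] is
#' lossless.
#'
#' @param ann An [ecg_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(ann, path) {
  jsonlite::write_json(list(beats = ann$beats, episodes = ann$episodes),
                       path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write an ECG record as two-column CSV
#'
#' Rows are `(time_s, mV)`; [read_record()] recovers the sampling rate from
#' the time column.
#'
#' @param rec An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(rec, path) {
  t <- seq_along(rec$samples) - 1
  utils::write.table(data.frame(t / rec$fs, rec$samples), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
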