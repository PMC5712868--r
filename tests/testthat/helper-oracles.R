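# Independent oracles used across the suite. These re-derive expected
# values by direct definition (brute force, dense grids, per-sample
# counting) and deliberately share no code path with the package
# implementation they check.

# Brute-force sample entropy: per-template row scan over all later
# templates, Chebyshev distance accumulated lag by lag. O(N^2) work,
# structured completely differently from the package's full-matrix route.
sampen_bruteforce <- function(x, m, r) {
  N <- length(x)
  if (N <= m + 1) return(NA_real_)
  nt <- N - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    dm <- abs(x[js] - x[i])
    for (k in seq_len(m - 1L))
      dm <- pmax(dm, abs(x[js + k] - x[i + k]))
    B <- B + sum(dm <= r)
    dm1 <- pmax(dm, abs(x[js + m] - x[i + m]))
    A <- A + sum(dm1 <= r)
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Per-sample episode/duration counter: paints half-open intervals onto an
# integer grid and counts hits sample by sample.
episode_stats_persample <- function(ref, test, n) {
  paint <- function(eps) {
    v <- logical(n)
    for (k in seq_len(nrow(eps)))
      if (eps$end[k] > eps$start[k])
        v[(eps$start[k] + 1):eps$end[k]] <- TRUE
    v
  }
  rv <- paint(ref); tv <- paint(test)
  both <- rv & tv
  hit_ref <- vapply(seq_len(nrow(ref)), function(k)
    any(both[(ref$start[k] + 1):ref$end[k]]), logical(1))
  hit_test <- vapply(seq_len(nrow(test)), function(k)
    any(both[(test$start[k] + 1):test$end[k]]), logical(1))
  pct <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  list(ese = pct(sum(hit_ref), nrow(ref)),
       epp = pct(sum(hit_test), nrow(test)),
       dse = pct(sum(both), sum(rv)),
       dpp = pct(sum(both), sum(tv)))
}

# Raw periodogram by direct DFT definition (no fft call), |X_k|^2 / n of
# the mean-removed segment; returns the two-sided first half.
periodogram_dft <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  half <- floor(n / 2)
  k <- 0:half
  P <- vapply(k, function(kk) {
    w <- -2 * pi * kk * (0:(n - 1)) / n
    Mod(sum(complex(real = x * cos(w), imaginary = x * sin(w))))^2 / n
  }, numeric(1))
  list(freq = k * 1 / (n / 200), power = P)  # assumes fs = 200
}

# non-overlapping random episode set on [0, n)
random_episode_set <- function(n, max_eps = 4) {
  k <- sample.int(max_eps + 1, 1) - 1
  if (k == 0)
    return(data.frame(start = numeric(), end = numeric()))
  cuts <- sort(sample.int(n - 1, 2 * k))
  data.frame(start = cuts[seq(1, 2 * k, by = 2)],
             end = cuts[seq(2, 2 * k, by = 2)])
}

# reference annotation from detected beats, for scoring detector output
beats_as_annotation <- function(beats, labels = NULL) {
  if (is.null(labels)) labels <- rep("N", length(beats$beat_samples))
  ecg_annotation(beats = data.frame(sample = beats$beat_samples,
                                    label = labels))
}
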