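# Shared fixtures: tiny deterministic recordings and independent oracles.

# Recording holding one sinusoid per channel (same frequency, per-channel
# amplitude), for filter and referencing tests.
sine_recording <- function(freq_hz, fs = 250, duration_s = 30, amps = 1,
                           labels = NULL, types = NULL) {
  t <- (0:(duration_s * fs - 1)) / fs
  n_ch <- length(amps)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n_ch))
  x <- t(vapply(amps, function(a) a * sin(2 * pi * freq_hz * t),
                numeric(length(t))))
  new_recording(x, fs, labels, types = types)
}

# Hand-built MPF series: one value per 1-s window start, 2-s windows.
fake_mpf_series <- function(mpf, area_id = 1, band = c(1, 45),
                            subject_id = "fake") {
  structure(list(area_id = area_id, times_s = seq_along(mpf) - 1,
                 mpf_hz = mpf, window_s = 2, step_s = 1, band = band,
                 subject_id = subject_id, missing = FALSE),
            class = "mpf_series")
}

# Independent brute-force MPF oracle: cumulative half-power search with
# linear interpolation, written as a plain loop (no shared code path).
oracle_mpf <- function(freqs, power, fmin, fmax) {
  keep <- freqs >= fmin & freqs <= fmax
  f <- freqs[keep]; p <- power[keep]
  target <- sum(p) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (acc + p[i] >= target) {
      if (i == 1) return(f[1])
      return(f[i - 1] + (target - acc) / p[i] * (f[i] - f[i - 1]))
    }
    acc <- acc + p[i]
  }
  f[length(f)]
}

# Independent Spearman oracle: explicit average ranks, then Pearson formula.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# 18-channel montage subset (two channels per area) for mid-sized tests.
labels18 <- function() default_labels(18)
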