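#' One-sided power spectrum of a short segment
#'
#' Periodogram of a single analysis window. Power is normalized so that the
#' one-sided spectrum sums to the mean square of the (optionally demeaned,
#' optionally tapered) segment — i.e. Parseval holds exactly. Frequency
#' resolution is `1 / (length(segment) / fs)`, so a 2 s window at 250 Hz
#' gives 0.5 Hz bins.
#'
#' @param segment numeric vector, one analysis window of samples.
#' @param fs sampling rate in Hz.
#' @param detrend subtract the segment mean before transforming (default
#'   TRUE; the DC bin is not interpretable for EEG).
#' @param taper `"none"` (rectangular, the default) or `"hann"`.
#' @param window_start_s optional bookkeeping tag, seconds.
#' @return An `eeg_spectrum`: list with `freqs` (Hz, from 0) and `power`.
#' @export
psd_window <- function(segment, fs, detrend = TRUE,
                       taper = c("none", "hann"), window_start_s = NA_real_) {
  taper <- match.arg(taper)
  n <- length(segment)
  if (n < 2) stop("psd_window: segment too short", call. = FALSE)
  if (n %% 2 != 0)
    stop("psd_window: segment length must be even, got ", n, call. = FALSE)
  if (detrend) segment <- segment - mean(segment)
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)) else rep(1, n)
  X <- stats::fft(segment * w)
  p <- Mod(X)^2 / (n^2 * mean(w^2))
  half <- n / 2
  power <- c(p[1], 2 * p[2:half], p[half + 1])
  structure(list(freqs = fs * (0:half) / n, power = power, fs = fs,
                 window_start_s = window_start_s, taper = taper),
            class = "eeg_spectrum")
}

# Core half-power crossing on band-restricted bins; NA when the band holds
# no power. Shared by median_power_frequency() and the vectorized
# time-course path so both use identical interpolation arithmetic.
mpf_core <- function(fb, pb) {
  tot <- sum(pb)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  cs <- cumsum(pb)
  half <- tot / 2
  k <- which(cs >= half)[1]
  if (k == 1L) return(fb[1])
  prev <- cs[k - 1]
  fb[k - 1] + (half - prev) / (cs[k] - prev) * (fb[k] - fb[k - 1])
}

# One-sided power of every sliding window of x at once: returns bins x
# n_windows matrix normalized like psd_window() (Parseval per column).
window_power_matrix <- function(x, fs, starts, wlen, detrend = TRUE,
                                taper = "none") {
  idx <- outer(seq_len(wlen), round(starts * fs), `+`)
  W <- matrix(x[idx], nrow = wlen)
  if (detrend) W <- sweep(W, 2, colMeans(W))
  w <- if (taper == "hann")
    0.5 * (1 - cos(2 * pi * (0:(wlen - 1)) / wlen)) else rep(1, wlen)
  Fm <- stats::mvfft(W * w)
  half <- wlen / 2
  P <- Mod(Fm[1:(half + 1), , drop = FALSE])^2 / (wlen^2 * mean(w^2))
  P[2:half, ] <- 2 * P[2:half, , drop = FALSE]
  list(freqs = fs * (0:half) / wlen, power = P)
}

#' Median power frequency of a spectrum
#'
#' The frequency at which the cumulative power over `[fmin, fmax]`
#' (inclusive bin range) first reaches half the band total, linearly
#' interpolated inside the crossing bin. When the cumulative sum hits
#' exactly half at a bin, that (lower) bin frequency is returned.
#'
#' @param spec an `eeg_spectrum`, or any list with `freqs` and `power`.
#' @param fmin,fmax integration band in Hz (default 1-45).
#' @return MPF in Hz, guaranteed inside `[fmin, fmax]`; errors if the band
#'   holds no power.
#' @export
median_power_frequency <- function(spec, fmin = 1, fmax = 45) {
  f <- spec$freqs; p <- spec$power
  if (fmin >= fmax) stop("median_power_frequency: fmin must be < fmax", call. = FALSE)
  if (fmin < f[1] || fmax > f[length(f)])
    stop("median_power_frequency: band [", fmin, ", ", fmax,
         "] outside the spectrum range", call. = FALSE)
  sel <- which(f >= fmin & f <= fmax)
  out <- mpf_core(f[sel], p[sel])
  if (is.na(out))
    stop("median_power_frequency: no power in band (undefined MPF)",
         call. = FALSE)
  out
}

#' MPF time-course over sliding windows
#'
#' Slides a `window_s` window with `step_s` stride over each area signal
#' (window starts 0, step, 2*step, ... while the full window fits), computes
#' the periodogram of each window and its median power frequency over
#' `band`. Windows with zero band power are flagged `NA` (undefined MPF)
#' rather than dropped. Missing areas yield all-`NA` series.
#'
#' @param region a `region_series`.
#' @param window_s window length in seconds (default 2).
#' @param step_s stride in seconds (default 1, i.e. 1 s overlap).
#' @param band MPF integration band in Hz.
#' @param detrend,taper forwarded to [psd_window()].
#' @param .power precomputed per-area window power (internal, to share the
#'   FFT work with [relative_band_power()]).
#' @return List of 9 `mpf_series` objects (one per area), each a list with
#'   `area_id`, `times_s` (window starts), `mpf_hz`, `window_s`, `step_s`,
#'   `band`, `subject_id`, `missing`.
#' @export
mpf_timecourse <- function(region, window_s = 2, step_s = 1, band = c(1, 45),
                           detrend = TRUE, taper = "none", .power = NULL) {
  stopifnot(inherits(region, "region_series"))
  fs <- region$fs
  dur <- ncol(region$samples) / fs
  if (dur < window_s)
    stop("recording (", dur, " s) shorter than the analysis window (",
         window_s, " s)", call. = FALSE)
  starts <- seq(0, dur - window_s, by = step_s)
  nwin <- length(starts)
  wlen <- round(window_s * fs)
  lapply(1:9, function(a) {
    missing <- a %in% region$missing
    mpf <- rep(NA_real_, nwin)
    if (!missing) {
      pm <- if (is.null(.power))
        window_power_matrix(region$samples[a, ], fs, starts, wlen,
                            detrend = detrend, taper = taper) else .power[[a]]
      sel <- which(pm$freqs >= band[1] & pm$freqs <= band[2])
      fb <- pm$freqs[sel]
      for (i in seq_len(nwin)) mpf[i] <- mpf_core(fb, pm$power[sel, i])
    }
    structure(list(area_id = a, times_s = starts, mpf_hz = mpf,
                   window_s = window_s, step_s = step_s, band = band,
                   subject_id = region$subject_id, missing = missing),
              class = "mpf_series")
  })
}

#' @export
print.mpf_series <- function(x, ...) {
  cat(sprintf("<mpf_series> area %d: %d windows (%g s / %g s), band %g-%g Hz\n",
              x$area_id, length(x$times_s), x$window_s, x$step_s,
              x$band[1], x$band[2]))
  invisible(x)
}

#' Canonical EEG band definitions
#'
#' delta 1-5, theta 5-8, alpha 8-12, beta 12-20 Hz. Band membership is
#' half-open `[low, high)` so shared edges (e.g. 5 Hz) are never counted
#' twice.
#'
#' @return Named list of `(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 5), theta = c(5, 8), alpha = c(8, 12), beta = c(12, 20))
}

#' Relative band power per area
#'
#' Welch-style average of the sliding-window periodograms (same windows as
#' the MPF time-course), then for each band the area under the averaged
#' spectrum divided by the area under `total_band`. Band bins are assigned
#' half-open `[low, high)`.
#'
#' @param region a `region_series`.
#' @param bands named list of band edges (default [eeg_bands()]).
#' @param total_band normalization band in Hz.
#' @param window_s,step_s,detrend,taper as in [mpf_timecourse()].
#' @param .power precomputed per-area window power (internal).
#' @return Data frame: `area_id`, one column per band (relative power in
#'   `[0, 1]`; `NA` for missing areas).
#' @export
relative_band_power <- function(region, bands = eeg_bands(),
                                total_band = c(1, 45), window_s = 2,
                                step_s = 1, detrend = TRUE, taper = "none",
                                .power = NULL) {
  stopifnot(inherits(region, "region_series"))
  fs <- region$fs
  dur <- ncol(region$samples) / fs
  if (dur < window_s)
    stop("recording shorter than the analysis window", call. = FALSE)
  starts <- seq(0, dur - window_s, by = step_s)
  wlen <- round(window_s * fs)
  out <- data.frame(area_id = 1:9)
  for (b in names(bands)) out[[b]] <- NA_real_
  for (a in 1:9) {
    if (a %in% region$missing) next
    pm <- if (is.null(.power))
      window_power_matrix(region$samples[a, ], fs, starts, wlen,
                          detrend = detrend, taper = taper) else .power[[a]]
    pw <- rowMeans(pm$power)
    f <- pm$freqs
    tot <- sum(pw[f >= total_band[1] & f < total_band[2]])
    if (tot <= 0) stop("relative_band_power: zero total power in area ", a,
                       call. = FALSE)
    for (b in names(bands)) {
      e <- bands[[b]]
      out[out$area_id == a, b] <- sum(pw[f >= e[1] & f < e[2]]) / tot
    }
  }
  out
}
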