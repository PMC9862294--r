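#' @name filters
#' @title Windowed-sinc FIR design and zero-phase filtering
#'
#' @description
#' The preprocessing filters are linear-phase FIRs designed by the
#' Hamming-window method. Filter length follows the standard transition-width
#' rule for the Hamming window (normalized transition ~ 3.3 / N), and the
#' -6 dB cutoffs are placed half a transition width outside the requested
#' passband edges so that the passband holds its gain at the stated edges
#' and the stopband reaches full attenuation one transition width beyond
#' them. Application is single-pass with the constant group delay removed,
#' which for symmetric taps is exactly zero-phase and leaves the magnitude
#' response equal to the designed |H(f)|.
NULL

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Hamming-rule tap count for a given transition width (odd).
fir_length <- function(transition_hz, fs) {
  n <- ceiling(3.3 * fs / transition_hz)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

# Windowed-sinc lowpass, cutoff at -6 dB point fc_hz, unity DC gain.
fir_lowpass_taps <- function(fc_hz, fs, transition_hz) {
  n <- fir_length(transition_hz, fs)
  m <- seq_len(n) - (n + 1) / 2
  h <- (2 * fc_hz / fs) * sinc(2 * fc_hz / fs * m) * hamming_window(n)
  h / sum(h)
}

# Unit impulse of odd length n (identity filter).
fir_delta_taps <- function(n) {
  h <- numeric(n)
  h[(n + 1) / 2] <- 1
  h
}

# Centre-align a shorter symmetric filter inside length n.
fir_pad_center <- function(h, n) {
  pad <- (n - length(h)) / 2
  c(numeric(pad), h, numeric(pad))
}

#' Filter specification
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param low_hz,high_hz band edges in Hz (the passband for a bandpass, the
#'   stop region for a bandstop).
#' @param transition_hz transition width(s) in Hz; for a bandpass a length-2
#'   vector (low edge, high edge) is accepted. Defaults: 1 Hz at a band edge
#'   at or below 2 Hz, 2 Hz elsewhere.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("bandpass", "bandstop"), low_hz, high_hz,
                        transition_hz = NULL) {
  kind <- match.arg(kind)
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("filter band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  if (is.null(transition_hz))
    transition_hz <- c(if (low_hz <= 2) 1 else 2, 2)
  transition_hz <- rep_len(transition_hz, 2L)
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 transition_hz = transition_hz),
            class = "filter_spec")
}

#' Design the taps for a filter specification
#'
#' Bandpass: convolution of a highpass (spectral inversion of a lowpass cut
#' half a transition below the low edge) with a lowpass cut half a
#' transition above the high edge. Bandstop: sum of a lowpass cut half a
#' transition inside the low edge and the matching highpass, giving a unity
#' passband outside `[low_hz, high_hz]`.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @return Numeric vector of symmetric (linear-phase) taps, odd length.
#' @export
fir_design <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_hz >= fs / 2)
    stop("band edge ", spec$high_hz, " Hz is at or above Nyquist (",
         fs / 2, " Hz)", call. = FALSE)
  tl <- spec$transition_hz[1]; th <- spec$transition_hz[2]
  if (spec$kind == "bandpass") {
    fc1 <- max(spec$low_hz - tl / 2, tl / 100)
    lp1 <- fir_lowpass_taps(fc1, fs, tl)
    hp <- fir_delta_taps(length(lp1)) - lp1
    lp2 <- fir_lowpass_taps(spec$high_hz + th / 2, fs, th)
    stats::convolve(hp, rev(lp2), type = "open")
  } else {
    tw <- tl
    lp <- fir_lowpass_taps(spec$low_hz + tw / 2, fs, tw)
    lp2 <- fir_lowpass_taps(spec$high_hz - tw / 2, fs, tw)
    n <- max(length(lp), length(lp2))
    fir_pad_center(lp, n) + fir_delta_taps(n) - fir_pad_center(lp2, n)
  }
}

#' Magnitude response of FIR taps
#'
#' Direct evaluation of |H(f)| = |sum_k h_k exp(-2 pi i f k / fs)| on an
#' arbitrary frequency grid; used both by the filtering contract tests and
#' as the independent design oracle.
#'
#' @param taps FIR coefficients.
#' @param freqs_hz frequencies at which to evaluate (Hz).
#' @param fs sampling rate in Hz.
#' @return Numeric vector of magnitudes (linear gain).
#' @export
fir_response <- function(taps, freqs_hz, fs) {
  k <- seq_along(taps) - 1
  vapply(freqs_hz,
         function(f) Mod(sum(taps * exp(-2i * pi * f * k / fs))),
         numeric(1))
}

# FFT overlap-free convolution of every column of X (time x channels) with
# taps, returning the zero-phase (delay-compensated) result, same size.
# Columns are reflection-padded (filtfilt-style odd reflection) to suppress
# edge transients.
apply_fir_cols <- function(X, taps) {
  n <- nrow(X); p <- length(taps); d <- (p - 1) / 2
  if (n < 3 * p)
    stop("recording too short for this filter: ", n, " samples < 3 x ",
         p, " taps", call. = FALSE)
  front <- 2 * X[rep(1L, p), , drop = FALSE] - X[(p + 1):2, , drop = FALSE]
  back <- 2 * X[rep(n, p), , drop = FALSE] - X[(n - 1):(n - p), , drop = FALSE]
  Xp <- rbind(front, X, back)
  np <- nrow(Xp)
  nfft <- stats::nextn(np + p - 1, 2)
  H <- stats::fft(c(taps, numeric(nfft - p)))
  Xf <- stats::mvfft(rbind(Xp, matrix(0, nfft - np, ncol(X))))
  Y <- Re(stats::mvfft(Xf * H, inverse = TRUE)) / nfft
  Y[p + d + seq_len(n), , drop = FALSE]
}

#' Zero-phase FIR filtering of a recording
#'
#' Designs the taps for `spec` at the recording's sampling rate and applies
#' them to every channel with zero phase (symmetric linear-phase taps,
#' group delay compensated). Shape, sampling rate, labels and types are
#' preserved.
#'
#' @param rec an `eeg_recording`.
#' @param spec a [filter_spec()].
#' @return The filtered `eeg_recording`.
#' @export
fir_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"))
  taps <- fir_design(spec, rec$fs)
  rec$samples <- t(apply_fir_cols(t(rec$samples), taps))
  rownames(rec$samples) <- rec$labels
  rec
}
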