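#' @name edf
#' @title Minimal EDF reader/writer
#'
#' @description
#' Just enough of the European Data Format (EDF): a fixed 256-byte ASCII
#' header, one 256-byte ASCII block per signal, then contiguous data
#' records of little-endian 16-bit integers with per-signal linear
#' physical scaling. All signals must share one sampling rate, the record
#' duration is fixed at 1 s, and the recording is truncated to whole
#' seconds on write. Roundtrips are exact up to the 16-bit quantization
#' step (physical range / 65535 per channel).
NULL

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = "-")
}

# Format a number to fit an 8-char ASCII field losslessly enough that
# re-parsing the field reproduces the value used for scaling.
edf_num8 <- function(x) {
  s <- sprintf("%g", x)
  bad <- nchar(s) > 8
  s[bad] <- sprintf("%.1e", x[bad])
  s
}

#' Write a recording to an EDF file
#'
#' @param rec an `eeg_recording` with integer sampling rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs))
    stop("write_edf: non-integer sampling rates unsupported", call. = FALSE)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("write_edf: recording shorter than 1 s", call. = FALSE)
  if (n_rec * fs < ncol(rec$samples))
    warning("write_edf: truncating to ", n_rec, " whole seconds")
  ns <- n_channels(rec)
  X <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmax_ <- apply(abs(X), 1, max)
  pmax_[pmax_ == 0] <- 1
  # headroom > the 4-digit rounding error, and re-parse the header string so
  # the scale used for quantization is exactly what read_edf will see
  pmax_ <- abs(as.numeric(edf_num8(signif(pmax_ * 1.001, 4))))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste0(s, collapse = ""), con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad("pswer synthetic/processed EEG", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  wr(edf_pad(rec$labels, 16))
  wr(edf_pad(rep("", ns), 80))
  wr(edf_pad(rep("uV", ns), 8))
  wr(edf_pad(edf_num8(-pmax_), 8)); wr(edf_pad(edf_num8(pmax_), 8))
  # symmetric digital range so 0 uV is exactly representable
  wr(edf_pad(rep("-32767", ns), 8)); wr(edf_pad(rep("32767", ns), 8))
  wr(edf_pad(rep("", ns), 80))
  wr(edf_pad(rep(fs, ns), 8))
  wr(edf_pad(rep("", ns), 32))

  # same affine map the reader applies: phys = (d - dmin) * gain + pmin
  gain <- 2 * pmax_ / 65534
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    block <- round(X[, idx, drop = FALSE] / gain)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param eog_pattern label pattern used to tag EOG channels.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, eog_pattern = "^EOG") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                   # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)           # reserved
  if (length(unique(spr)) != 1)
    stop("read_edf: mixed per-signal sampling rates unsupported",
         call. = FALSE)
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  X <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = spr[1], ncol = ns)
    idx <- (r - 1) * spr[1] + seq_len(spr[1])
    X[, idx] <- t(block * rep(gain, each = spr[1]) +
                    rep(pmin_ - dmin_ * gain, each = spr[1]))
  }
  new_recording(X, fs, labels, subject_id = subject_id,
                eog_pattern = eog_pattern)
}
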