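#' Remove channels by label
#'
#' Input-driven replacement for visual-inspection channel rejection: bad
#' channels are named in a per-subject exclusion list.
#'
#' @param rec an `eeg_recording`.
#' @param bad_labels labels to drop (must all exist); the empty vector is a
#'   no-op.
#' @return The recording without those channels, order preserved.
#' @export
exclude_channels <- function(rec, bad_labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad_labels <- as.character(bad_labels)
  unknown <- setdiff(bad_labels, rec$labels)
  if (length(unknown))
    stop("cannot exclude unknown channel(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!length(bad_labels)) return(rec)
  keep <- !(rec$labels %in% bad_labels)
  rec$samples <- rec$samples[keep, , drop = FALSE]
  rec$labels <- rec$labels[keep]
  rec$types <- rec$types[keep]
  rec
}

#' Average re-referencing
#'
#' Subtracts the instantaneous mean of all EEG-typed channels from each
#' EEG channel; EOG channels are untouched. Idempotent, and forces the
#' per-sample EEG mean to zero.
#'
#' @param rec an `eeg_recording` with at least two EEG channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  eeg <- rec$types == "EEG"
  if (sum(eeg) < 2)
    stop("average reference needs at least 2 EEG channels, found ",
         sum(eeg), call. = FALSE)
  ref <- colMeans(rec$samples[eeg, , drop = FALSE])
  rec$samples[eeg, ] <- sweep(rec$samples[eeg, , drop = FALSE], 2, ref)
  rec
}

#' Drop EOG channels
#'
#' @param rec an `eeg_recording`.
#' @return The recording with only EEG-typed channels (no-op if none are
#'   EOG).
#' @export
drop_eog <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- rec$types == "EEG"
  if (all(keep)) return(rec)
  rec$samples <- rec$samples[keep, , drop = FALSE]
  rec$labels <- rec$labels[keep]
  rec$types <- rec$types[keep]
  rec
}

#' Standard preprocessing chain
#'
#' Fixed stage order: band-pass, band-stop, channel exclusion, average
#' re-reference, EOG removal. Defaults follow the recording protocol this
#' pipeline targets: 1-95 Hz FIR band-pass and a 45-55 Hz band-stop for
#' 50 Hz mains (set `bandstop = c(55, 65)` in 60 Hz regions). ICA-style
#' artifact correction is intentionally not part of the chain; feed
#' externally cleaned recordings if needed.
#'
#' @param rec an `eeg_recording`.
#' @param bandpass passband edges in Hz, or `NULL` to skip.
#' @param bandstop stop-band edges in Hz, or `NULL` to skip.
#' @param exclude labels to remove after filtering.
#' @return The preprocessed `eeg_recording` (EEG channels only).
#' @export
preprocess_recording <- function(rec, bandpass = c(1, 95),
                                 bandstop = c(45, 55),
                                 exclude = character()) {
  taps <- NULL
  if (!is.null(bandpass))
    taps <- fir_design(filter_spec("bandpass", bandpass[1], bandpass[2]),
                       rec$fs)
  if (!is.null(bandstop)) {
    bs <- fir_design(filter_spec("bandstop", bandstop[1], bandstop[2]),
                     rec$fs)
    # cascade the two linear-phase filters as one convolution pass
    taps <- if (is.null(taps)) bs else
      stats::convolve(taps, rev(bs), type = "open")
  }
  if (!is.null(taps)) {
    rec$samples <- t(apply_fir_cols(t(rec$samples), taps))
    rownames(rec$samples) <- rec$labels
  }
  rec <- exclude_channels(rec, exclude)
  rec <- rereference_average(rec)
  drop_eog(rec)
}
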