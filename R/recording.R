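#' Multi-channel EEG recording
#'
#' Lightweight in-memory container for a scalp EEG recording: a channels x
#' time sample matrix in microvolts plus the metadata every downstream stage
#' needs (sampling rate, ordered channel labels, per-channel type tags, and
#' an optional truth log of planted events used by the synthetic generator).
#'
#' @param samples numeric matrix, channels in rows, samples in columns (uV).
#' @param fs sampling rate in Hz.
#' @param labels character vector of channel names, one per row, no
#'   duplicates.
#' @param types per-channel tag, `"EEG"` or `"EOG"`. Defaults to a
#'   label-pattern rule: labels matching `eog_pattern` are tagged EOG.
#' @param subject_id subject identifier.
#' @param events optional data frame of planted ground-truth events (see
#'   [plant_slow_event()]); `NULL` for real recordings.
#' @param eog_pattern regular expression used to tag EOG channels when
#'   `types` is not given.
#'
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(samples, fs, labels, types = NULL,
                          subject_id = "subject", events = NULL,
                          eog_pattern = "^EOG") {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x time)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(samples))
    stop("`labels` length (", length(labels), ") must equal the number of ",
         "channel rows (", nrow(samples), ")", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (is.null(types)) {
    types <- ifelse(grepl(eog_pattern, labels), "EOG", "EEG")
  } else {
    types <- as.character(types)
    if (length(types) != length(labels))
      stop("`types` must have one entry per channel", call. = FALSE)
    bad <- setdiff(unique(types), c("EEG", "EOG"))
    if (length(bad))
      stop("unknown channel types: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  rownames(samples) <- labels
  structure(
    list(samples = samples, fs = fs, labels = labels, types = types,
         subject_id = subject_id, events = events),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject '%s': %d channels x %d samples (%.1f s @ %g Hz)\n",
              x$subject_id, n_channels(x), ncol(x$samples),
              duration_s(x), x$fs))
  cat(sprintf("  types: %d EEG, %d EOG\n",
              sum(x$types == "EEG"), sum(x$types == "EOG")))
  if (!is.null(x$events) && nrow(x$events))
    cat(sprintf("  truth log: %d planted event(s)\n", nrow(x$events)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return Length of the recording in seconds.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' Number of channels in a recording
#' @param rec an `eeg_recording`.
#' @return Integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$samples)

# Internal: root mean square.
rms <- function(x) sqrt(mean(x^2))

#' Nine regional average signals
#'
#' Container produced by [spatial_average()]: one row per anatomical area in
#' fixed area order 1..9. Areas whose member channels were all excluded are
#' kept as rows of `NA` and flagged in `missing`.
#'
#' @param samples 9 x time numeric matrix (uV), rows in area order.
#' @param fs sampling rate in Hz.
#' @param area_names character vector of the 9 area names.
#' @param subject_id subject identifier.
#' @param missing integer vector of area ids with no member channels.
#' @return An object of class `region_series`.
#' @export
new_region_series <- function(samples, fs, area_names = area_names_default(),
                              subject_id = "subject", missing = integer()) {
  stopifnot(is.matrix(samples), nrow(samples) == 9L)
  structure(
    list(samples = samples, fs = fs, area_ids = 1:9,
         area_names = area_names, subject_id = subject_id,
         missing = as.integer(missing)),
    class = "region_series")
}

#' @export
print.region_series <- function(x, ...) {
  cat(sprintf("<region_series> subject '%s': 9 areas x %d samples (%.1f s @ %g Hz)\n",
              x$subject_id, ncol(x$samples), ncol(x$samples) / x$fs, x$fs))
  if (length(x$missing))
    cat("  missing areas:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
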