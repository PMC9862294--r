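#' Names of the nine anatomical areas
#'
#' Fixed numbering: right/left/central within frontal, tempo-parietal and
#' occipital strips (area 1 = right frontal ... area 9 = central occipital).
#'
#' @return Character vector of length 9, names in area-id order.
#' @export
area_names_default <- function() {
  c("right frontal", "left frontal", "central frontal",
    "right tempo-parietal", "left tempo-parietal", "central tempo-parietal",
    "right occipital", "left occipital", "central occipital")
}

# The shipped 60-electrode 10-10 subset, grouped by area. The per-area
# counts are 8/8/2/15/15/4/3/3/2 for areas 1..9.
montage_labels_60 <- function() {
  c(# frontal right / left / midline
    "Fp2", "AF4", "AF8", "F2", "F4", "F6", "F8", "F10",
    "Fp1", "AF3", "AF7", "F1", "F3", "F5", "F7", "F9",
    "Fpz", "Fz",
    # tempo-parietal right / left / midline
    "FC2", "FC4", "FC6", "C2", "C4", "C6", "T8",
    "CP2", "CP4", "CP6", "TP8", "P2", "P4", "P6", "P8",
    "FC1", "FC3", "FC5", "C1", "C3", "C5", "T7",
    "CP1", "CP3", "CP5", "TP7", "P1", "P3", "P5", "P7",
    "FCz", "Cz", "CPz", "Pz",
    # occipital right / left / midline
    "PO4", "PO8", "O2",
    "PO3", "PO7", "O1",
    "POz", "Oz")
}

#' Default channel labels for synthetic recordings
#'
#' Returns `n` labels drawn from the packaged 60-name 10-10 subset,
#' interleaved across the nine areas so that any prefix of the list covers
#' all areas as evenly as possible (`n = 9` gives one channel per area).
#'
#' @param n number of labels (1..60).
#' @return Character vector of `n` channel labels.
#' @export
default_labels <- function(n = 60) {
  labs <- montage_labels_60()
  if (n < 1 || n > length(labs))
    stop("`n` must be between 1 and ", length(labs), call. = FALSE)
  m <- default_montage()
  area <- m$assignment[labs]
  # round-robin across areas
  ord <- order(stats::ave(seq_along(labs), area, FUN = seq_along), area)
  labs[ord][seq_len(n)]
}

#' Rule-based montage: 10-10 labels to nine areas
#'
#' Builds the electrode-to-area assignment from label semantics alone:
#' a trailing `z` marks the midline (central), otherwise an odd final digit
#' marks the left and an even digit the right hemisphere; the letter prefix
#' selects the strip (F/AF/Fp frontal; C/T/P/CP/TP/FC tempo-parietal;
#' O/PO occipital). The original study's exact appendix table is not
#' public, so this documented rule stands in for it and can be replaced via
#' [read_montage()].
#'
#' @param labels channel labels to assign (default: the shipped 60).
#' @return An object of class `montage_map`: list with `assignment` (named
#'   integer vector, label -> area id 1..9) and `area_names`.
#' @export
default_montage <- function(labels = montage_labels_60()) {
  strip_of <- function(prefix) {
    if (prefix %in% c("F", "AF", "Fp")) return("frontal")
    if (prefix %in% c("C", "T", "P", "CP", "TP", "FC")) return("tempo-parietal")
    if (prefix %in% c("O", "PO")) return("occipital")
    NA_character_
  }
  assignment <- vapply(labels, function(lab) {
    prefix <- sub("(z|[0-9]+)$", "", lab)
    strip <- strip_of(prefix)
    if (is.na(strip))
      stop("cannot assign channel '", lab, "' to an area: unknown prefix '",
           prefix, "'", call. = FALSE)
    side <- if (grepl("z$", lab)) {
      "central"
    } else {
      digit <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", lab)))
      if (is.na(digit))
        stop("cannot assign channel '", lab, "': no trailing digit or 'z'",
             call. = FALSE)
      if (digit %% 2 == 1) "left" else "right"
    }
    base <- c(frontal = 0L, `tempo-parietal` = 3L, occipital = 6L)[[strip]]
    base + c(right = 1L, left = 2L, central = 3L)[[side]]
  }, integer(1))
  structure(list(assignment = assignment, area_names = area_names_default()),
            class = "montage_map")
}

#' @export
print.montage_map <- function(x, ...) {
  cat("<montage_map>", length(x$assignment), "channels in",
      length(unique(x$assignment)), "areas\n")
  invisible(x)
}

#' Read a montage from a delimited file
#'
#' Two-column CSV with a header row: `label, area_id` (area ids 1..9).
#' The packaged default lives at
#' `system.file("extdata", "montage_1010_60.csv", package = "pswer")`.
#'
#' @param path path to the CSV file.
#' @return A `montage_map`.
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "area_id") %in% names(df)))
    stop("montage file must have columns 'label' and 'area_id'", call. = FALSE)
  if (anyDuplicated(df$label))
    stop("montage file assigns a label twice", call. = FALSE)
  if (!all(df$area_id %in% 1:9))
    stop("montage area ids must be in 1..9", call. = FALSE)
  assignment <- as.integer(df$area_id)
  names(assignment) <- df$label
  structure(list(assignment = assignment, area_names = area_names_default()),
            class = "montage_map")
}

#' Average channels into nine anatomical areas
#'
#' Each area signal is the unweighted arithmetic mean of its raw member
#' channels (signals are deliberately not normalized before averaging).
#' Only EEG-typed channels participate. Areas left without any member
#' channel (e.g. after exclusions) become rows of `NA` and are listed in the
#' result's `missing` field rather than silently zeroed.
#'
#' @param rec an `eeg_recording`.
#' @param map a `montage_map` (default [default_montage()]).
#' @param ignore labels allowed to be absent from the montage (dropped);
#'   any other unmapped EEG channel is an error.
#' @return A `region_series` with 9 rows in area order.
#' @export
spatial_average <- function(rec, map = default_montage(), ignore = character()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(map, "montage_map"))
  eeg <- rec$labels[rec$types == "EEG"]
  eeg <- setdiff(eeg, ignore)
  unmapped <- setdiff(eeg, names(map$assignment))
  if (length(unmapped))
    stop("channels not present in montage: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  out <- matrix(NA_real_, nrow = 9, ncol = ncol(rec$samples))
  missing <- integer()
  for (a in 1:9) {
    members <- intersect(eeg, names(map$assignment)[map$assignment == a])
    if (!length(members)) {
      missing <- c(missing, a)
    } else {
      out[a, ] <- colMeans(rec$samples[members, , drop = FALSE])
    }
  }
  new_region_series(out, rec$fs, map$area_names, rec$subject_id, missing)
}

#' Write the default montage to a CSV file
#'
#' Convenience used to regenerate the packaged `montage_1010_60.csv`.
#'
#' @param path output path.
#' @param map montage to write.
#' @return `path`, invisibly.
#' @export
write_montage <- function(path, map = default_montage()) {
  df <- data.frame(label = names(map$assignment),
                   area_id = unname(map$assignment))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
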