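#' Detect paroxysmal slow-wave events in an MPF time-course
#'
#' An event is a maximal run of consecutive sliding windows whose MPF is
#' strictly below `threshold_hz`, lasting at least `min_duration_s`. With
#' 2 s windows and 1 s stride, a run of `m` windows spans from the start of
#' its first window to the end of its last, i.e. `m + 1` seconds, so the
#' canonical "below 6 Hz for 5 consecutive seconds" means runs of 4 or more
#' windows. Windows with undefined MPF (`NA`) break runs.
#'
#' @param series an `mpf_series` (one area), or a list of them.
#' @param threshold_hz MPF threshold in Hz (must lie inside the series'
#'   integration band).
#' @param min_duration_s minimum event span in seconds.
#' @return Data frame of events: `subject_id`, `area_id`, `start_s`,
#'   `end_s`, `duration_s`, `mean_mpf_hz` (zero rows if none).
#' @export
detect_pswe <- function(series, threshold_hz = 6, min_duration_s = 5) {
  if (is.list(series) && !inherits(series, "mpf_series"))
    return(do.call(rbind, lapply(series, detect_pswe,
                                 threshold_hz = threshold_hz,
                                 min_duration_s = min_duration_s)))
  stopifnot(inherits(series, "mpf_series"))
  if (threshold_hz <= series$band[1] || threshold_hz >= series$band[2])
    stop("threshold ", threshold_hz, " Hz outside the MPF band (",
         series$band[1], ", ", series$band[2], ")", call. = FALSE)
  empty <- data.frame(subject_id = character(), area_id = integer(),
                      start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), mean_mpf_hz = numeric(),
                      stringsAsFactors = FALSE)
  sub <- !is.na(series$mpf_hz) & series$mpf_hz < threshold_hz
  if (!any(sub)) return(empty)
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in which(r$values)) {
    i1 <- starts[j]; i2 <- ends[j]
    t0 <- series$times_s[i1]
    t1 <- series$times_s[i2] + series$window_s
    if (t1 - t0 >= min_duration_s)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = series$subject_id, area_id = series$area_id,
        start_s = t0, end_s = t1, duration_s = t1 - t0,
        mean_mpf_hz = mean(series$mpf_hz[i1:i2]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Events per minute
#'
#' @param events event data frame from [detect_pswe()] (or any subset).
#' @param analyzed_duration_s analyzed recording length in seconds (> 0).
#' @return Event count divided by analyzed minutes.
#' @export
events_per_minute <- function(events, analyzed_duration_s) {
  if (!(analyzed_duration_s > 0))
    stop("events_per_minute: `analyzed_duration_s` must be > 0", call. = FALSE)
  nrow(events) / (analyzed_duration_s / 60)
}

# Internal: percentage of [0, dur] covered by the (disjoint) events of ONE
# area. Errors on overlap, tolerating shared endpoints.
pct_time_one_area <- function(events, dur) {
  if (!nrow(events)) return(0)
  if (any(events$start_s < -1e-9) || any(events$end_s > dur + 1e-9))
    stop("event outside [0, analyzed duration]", call. = FALSE)
  o <- order(events$start_s)
  s <- events$start_s[o]; e <- events$end_s[o]
  if (any(s[-1] < e[-length(e)] - 1e-9))
    stop("overlapping events within one area", call. = FALSE)
  100 * sum(e - s) / dur
}

#' Percentage of analyzed time spent inside PSWEs
#'
#' Per area: covered seconds / analyzed seconds x 100. Subject level
#' (the default): the mean of the per-area percentages over `areas`.
#'
#' @param events event data frame (may span several areas).
#' @param analyzed_duration_s analyzed recording length in seconds.
#' @param scope `"subject"` for a single number, `"area"` for a data frame
#'   with one row per area in `areas`.
#' @param areas area ids considered (default 1:9).
#' @return Percent in `[0, 100]`, or a data frame of them.
#' @export
percent_time_in_pswe <- function(events, analyzed_duration_s,
                                 scope = c("subject", "area"), areas = 1:9) {
  scope <- match.arg(scope)
  if (!(analyzed_duration_s > 0))
    stop("percent_time_in_pswe: `analyzed_duration_s` must be > 0",
         call. = FALSE)
  per <- vapply(areas, function(a)
    pct_time_one_area(events[events$area_id == a, , drop = FALSE],
                      analyzed_duration_s), numeric(1))
  if (scope == "area")
    return(data.frame(area_id = areas, pct_time_pswe = per))
  mean(per)
}

#' Per-subject, per-area event metrics
#'
#' @param events event data frame from [detect_pswe()].
#' @param analyzed_duration_s analyzed recording length in seconds.
#' @param band_table optional output of [relative_band_power()] to join.
#' @param areas area ids to report.
#' @return Data frame keyed by `area_id` with `n_events`,
#'   `events_per_min`, `pct_time_pswe` (+ band columns when given), with
#'   the subject-level percent time as attribute `"subject_pct_time"`.
#' @export
subject_metrics <- function(events, analyzed_duration_s, band_table = NULL,
                            areas = 1:9) {
  out <- data.frame(area_id = areas)
  out$n_events <- vapply(areas, function(a)
    sum(events$area_id == a), numeric(1))
  out$events_per_min <- out$n_events / (analyzed_duration_s / 60)
  out$pct_time_pswe <- percent_time_in_pswe(events, analyzed_duration_s,
                                            scope = "area", areas)$pct_time_pswe
  out$analyzed_duration_s <- analyzed_duration_s
  if (!is.null(band_table)) out <- merge(out, band_table, by = "area_id")
  attr(out, "subject_pct_time") <-
    percent_time_in_pswe(events, analyzed_duration_s, scope = "subject",
                         areas)
  out
}

#' Re-run detection over a range of MPF thresholds
#'
#' Sweeps `detect_pswe()` over `thresholds` and tabulates subject-level
#' counts and coverage. Event counts need not be monotone in the threshold
#' (neighbouring runs merge); percent time is.
#'
#' @param series list of `mpf_series` (all areas of one subject), or one.
#' @param thresholds thresholds in Hz (default 2-8).
#' @param min_duration_s minimum event span in seconds.
#' @param analyzed_duration_s analyzed length in seconds; defaults to the
#'   span covered by the windows.
#' @return Data frame: `threshold_hz`, `n_events`, `events_per_min`,
#'   `pct_time_pswe` (subject level).
#' @export
threshold_sweep <- function(series, thresholds = 2:8, min_duration_s = 5,
                            analyzed_duration_s = NULL) {
  if (inherits(series, "mpf_series")) series <- list(series)
  if (is.null(analyzed_duration_s)) {
    s1 <- series[[1]]
    analyzed_duration_s <- max(s1$times_s) + s1$window_s
  }
  areas <- vapply(series, function(s) s$area_id, numeric(1))
  rows <- lapply(thresholds, function(th) {
    ev <- detect_pswe(series, threshold_hz = th,
                      min_duration_s = min_duration_s)
    data.frame(threshold_hz = th, n_events = nrow(ev),
               events_per_min = events_per_minute(ev, analyzed_duration_s),
               pct_time_pswe = percent_time_in_pswe(ev, analyzed_duration_s,
                                                    areas = areas))
  })
  do.call(rbind, rows)
}

#' Subject-level event count (areas merged)
#'
#' Counts events at subject granularity: detections whose time intervals
#' overlap across areas are treated as one physical event. Rationale: the
#' average reference redistributes a regionally coherent slow wave into
#' every other regional mean, so one event is often observed in several
#' areas at once; the per-area count sums these observations, while this
#' count collapses them. Both granularities are legitimate summaries; see
#' the methods vignette.
#'
#' @param events event data frame from [detect_pswe()] (one subject).
#' @return Integer count of merged (time-disjoint) events.
#' @export
merged_event_count <- function(events) {
  if (!nrow(events)) return(0L)
  o <- order(events$start_s)
  s <- events$start_s[o]; e <- events$end_s[o]
  n <- 1L; cur <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur) {
      n <- n + 1L
      cur <- e[i]
    } else {
      cur <- max(cur, e[i])
    }
  }
  n
}

#' Match detected events against a planted truth log
#'
#' A detected event recovers a planted one when their time intervals
#' overlap (and, if `same_area`, the areas agree). Because the average
#' reference redistributes a regionally coherent oscillation across all
#' other regional means, physically real "leakage" detections can co-occur
#' with a planted event in other areas; false-positive checks therefore
#' match on time overlap alone, sensitivity checks on time + area.
#'
#' @param detected data frame from [detect_pswe()].
#' @param truth truth log (`area_id`, `start_s`, `duration_s`).
#' @param same_area require matching area ids.
#' @return List: `recovered` (logical per truth row), `matched_detection`
#'   (logical per detected row).
#' @export
match_events <- function(detected, truth, same_area = TRUE) {
  t_start <- truth$start_s; t_end <- truth$start_s + truth$duration_s
  rec <- logical(nrow(truth)); mat <- logical(nrow(detected))
  for (i in seq_len(nrow(truth))) {
    hit <- detected$start_s < t_end[i] & detected$end_s > t_start[i]
    if (same_area) hit <- hit & detected$area_id == truth$area_id[i]
    rec[i] <- any(hit)
    mat <- mat | hit
  }
  list(recovered = rec, matched_detection = mat)
}
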