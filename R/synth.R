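#' Synthetic background specification
#'
#' Describes an eyes-closed resting-state background: power-law (1/f^a)
#' broadband noise synthesized in the frequency domain (random phases,
#' deterministic magnitude, so the periodogram slope is exact) plus a
#' posterior-dominant alpha rhythm modelled as a sinusoid whose phase is
#' shared within each anatomical area and independent across areas.
#'
#' @param n_channels number of channels (labels drawn from the packaged
#'   10-10 subset, interleaved across the nine areas).
#' @param duration_s recording length in seconds (default 240, i.e. 4 min).
#' @param fs sampling rate in Hz (default 250).
#' @param spectral_exponent power-law slope `a` of the background
#'   (power ~ 1/f^a); 1 is typical resting EEG, 0 gives flat noise.
#' @param alpha_freq alpha rhythm frequency in Hz.
#' @param alpha_rel_amp ratio of alpha RMS to background RMS (0 disables;
#'   1 emulates a prominent eyes-closed alpha).
#' @param bg_band frequency support of the background in Hz; the upper edge
#'   must stay below `fs / 2`.
#' @param background_rms broadband RMS amplitude in microvolts.
#' @param seed integer RNG seed.
#' @param labels optional explicit channel labels (default
#'   `default_labels(n_channels)`).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_channels = 60, duration_s = 240, fs = 250,
                       spectral_exponent = 1, alpha_freq = 10,
                       alpha_rel_amp = 1, bg_band = c(0.5, 95),
                       background_rms = 10, seed = 1, labels = NULL) {
  if (!(is.numeric(duration_s) && duration_s > 0))
    stop("synth_spec: `duration_s` must be > 0", call. = FALSE)
  if (!(is.numeric(n_channels) && n_channels >= 1))
    stop("synth_spec: `n_channels` must be >= 1", call. = FALSE)
  fmax <- max(bg_band[2], if (alpha_rel_amp > 0) alpha_freq else 0)
  if (!(fs > 2 * fmax))
    stop("synth_spec: `fs` must exceed twice the highest synthesized ",
         "frequency (", fmax, " Hz)", call. = FALSE)
  if (bg_band[1] <= 0 || bg_band[1] >= bg_band[2])
    stop("synth_spec: `bg_band` must satisfy 0 < low < high", call. = FALSE)
  if (is.null(labels)) labels <- default_labels(n_channels)
  if (length(labels) != n_channels)
    stop("synth_spec: `labels` must have `n_channels` entries", call. = FALSE)
  structure(list(n_channels = n_channels, duration_s = duration_s, fs = fs,
                 spectral_exponent = spectral_exponent,
                 alpha_freq = alpha_freq, alpha_rel_amp = alpha_rel_amp,
                 bg_band = bg_band, background_rms = background_rms,
                 seed = as.integer(seed), labels = labels),
            class = "synth_spec")
}

#' Generate a synthetic resting-state background recording
#'
#' Frequency-domain synthesis: each channel's one-sided spectrum has
#' magnitude `f^(-a/2)` on `bg_band` and independent uniform random phases;
#' the inverse FFT is scaled to `background_rms`. The alpha rhythm is added
#' in the time domain with a per-area random phase so that spatial
#' averaging preserves it while independent background noise averages out.
#' Bit-identical output for identical spec (including seed).
#'
#' @param spec a [synth_spec()].
#' @return An `eeg_recording` with an empty truth log.
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fs)
  if (n %% 2 == 1) n <- n - 1  # even length keeps the Nyquist bin explicit
  nc <- spec$n_channels
  freqs <- (1:(n / 2 - 1)) * spec$fs / n
  amp <- numeric(length(freqs))
  inband <- freqs >= spec$bg_band[1] & freqs <= spec$bg_band[2]
  amp[inband] <- freqs[inband]^(-spec$spectral_exponent / 2)

  # per-area alpha phases first, then per-channel background phases, so the
  # draw order (and thus reproducibility) is independent of channel count
  area_phase <- stats::runif(9, 0, 2 * pi)
  phases <- matrix(stats::runif(length(freqs) * nc, 0, 2 * pi),
                   nrow = length(freqs), ncol = nc)

  S <- amp * exp(1i * phases)                   # (n/2 - 1) x nc
  full <- matrix(0i, nrow = n, ncol = nc)
  full[2:(n / 2), ] <- S
  full[n:(n / 2 + 2), ] <- Conj(S)
  x <- Re(stats::mvfft(full, inverse = TRUE))   # n x nc
  sc <- spec$background_rms / sqrt(colMeans(x^2))
  x <- sweep(x, 2, sc, `*`)

  if (spec$alpha_rel_amp > 0) {
    areas <- default_montage(spec$labels)$assignment[spec$labels]
    tt <- (0:(n - 1)) / spec$fs
    a_amp <- sqrt(2) * spec$alpha_rel_amp * spec$background_rms
    for (ch in seq_len(nc))
      x[, ch] <- x[, ch] +
        a_amp * sin(2 * pi * spec$alpha_freq * tt + area_phase[areas[ch]])
  }

  new_recording(t(x), spec$fs, spec$labels, rep("EEG", nc),
                subject_id = "synthetic", events = empty_truth_log())
}

empty_truth_log <- function() {
  data.frame(subject_id = character(), area_id = integer(),
             channels = character(), start_s = numeric(),
             duration_s = numeric(), dominant_freq = numeric(),
             amplitude_ratio = numeric(), stringsAsFactors = FALSE)
}

#' Describe a slow-wave episode to plant
#'
#' @param channel_set channel labels carrying the oscillation.
#' @param start_s onset in seconds from recording start.
#' @param duration_s episode length in seconds.
#' @param dominant_freq oscillation frequency in Hz (a detectable slow wave
#'   has `dominant_freq` well below the 6 Hz MPF threshold).
#' @param amplitude_ratio ratio of the oscillation's RMS to the carrying
#'   channel's current RMS (0 plants nothing).
#' @return A `planted_event` list.
#' @export
planted_event <- function(channel_set, start_s, duration_s, dominant_freq,
                          amplitude_ratio) {
  if (start_s < 0) stop("planted_event: `start_s` must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("planted_event: `duration_s` must be > 0", call. = FALSE)
  if (dominant_freq <= 0) stop("planted_event: `dominant_freq` must be > 0", call. = FALSE)
  if (amplitude_ratio < 0) stop("planted_event: `amplitude_ratio` must be >= 0", call. = FALSE)
  structure(list(channel_set = as.character(channel_set), start_s = start_s,
                 duration_s = duration_s, dominant_freq = dominant_freq,
                 amplitude_ratio = amplitude_ratio),
            class = "planted_event")
}

#' Plant a slow-wave episode into a recording
#'
#' Adds a sinusoid at `dominant_freq` to the named channels over
#' `[start_s, start_s + duration_s]`, with a 0.5 s raised-cosine
#' onset/offset taper (shortened for very brief events) to avoid broadband
#' edge clicks. The oscillation is coherent (same phase) across the target
#' channels, emulating a regionally synchronous slow wave. The event is
#' appended to the recording's truth log; all other samples are unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param ev a [planted_event()].
#' @return A modified copy of `rec`.
#' @export
plant_slow_event <- function(rec, ev) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(ev, "planted_event"))
  if (ev$start_s + ev$duration_s > duration_s(rec) + 1e-9)
    stop("planted event [", ev$start_s, ", ", ev$start_s + ev$duration_s,
         "] s exceeds the ", duration_s(rec), " s recording", call. = FALSE)
  unknown <- setdiff(ev$channel_set, rec$labels)
  if (length(unknown))
    stop("planted event names unknown channel(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  i0 <- floor(ev$start_s * rec$fs)
  len <- min(round(ev$duration_s * rec$fs), ncol(rec$samples) - i0)
  idx <- i0 + seq_len(len)
  t_rel <- (seq_len(len) - 1) / rec$fs
  ramp <- min(0.5, ev$duration_s / 2)
  w <- rep(1, len)
  nr <- round(ramp * rec$fs)
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr))
    w[seq_len(nr)] <- up
    w[len + 1 - seq_len(nr)] <- up
  }
  osc <- sin(2 * pi * ev$dominant_freq * t_rel) * w
  if (ev$amplitude_ratio > 0) {
    for (ch in ev$channel_set) {
      a <- sqrt(2) * ev$amplitude_ratio * rms(rec$samples[ch, ])
      rec$samples[ch, idx] <- rec$samples[ch, idx] + a * osc
    }
  }
  area <- tryCatch({
    ar <- default_montage(ev$channel_set)$assignment
    as.integer(names(sort(table(ar), decreasing = TRUE))[1])
  }, error = function(e) NA_integer_)
  if (is.null(rec$events)) rec$events <- empty_truth_log()
  rec$events <- rbind(rec$events, data.frame(
    subject_id = rec$subject_id, area_id = area,
    channels = paste(ev$channel_set, collapse = ";"),
    start_s = ev$start_s, duration_s = ev$duration_s,
    dominant_freq = ev$dominant_freq,
    amplitude_ratio = ev$amplitude_ratio, stringsAsFactors = FALSE))
  rec
}

#' Cohort specification for the synthetic generator
#'
#' Defines a cohort whose per-subject slow-wave event rate is linearly
#' linked to a disease-duration-like covariate:
#' `rate = max(0, base_event_rate + rate_covariate_slope * covariate)`
#' events/min, events drawn as a Poisson process and placed without overlap
#' within an area.
#'
#' @param n_subjects_per_group subjects per group.
#' @param groups group labels.
#' @param base_event_rate events/min at covariate 0; scalar or one value
#'   per group.
#' @param rate_covariate_slope events/min change per covariate unit (years).
#' @param covariate_range uniform sampling range of the covariate (years).
#' @param event_duration_range_s event durations, drawn uniformly (s).
#' @param event_freq_range_hz event dominant frequencies, drawn uniformly (Hz).
#' @param amplitude_ratio RMS ratio of planted events to background.
#' @param synth a [synth_spec()] describing each subject's background.
#' @param seed integer RNG seed for the cohort draw.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects_per_group = 31, groups = c("PD", "HC"),
                        base_event_rate = 0.5, rate_covariate_slope = 0.08,
                        covariate_range = c(0, 10),
                        event_duration_range_s = c(7, 15),
                        event_freq_range_hz = c(1, 4),
                        amplitude_ratio = 5,
                        synth = synth_spec(), seed = 1) {
  if (any(base_event_rate < 0))
    stop("cohort_spec: `base_event_rate` must be >= 0", call. = FALSE)
  for (r in list(covariate_range, event_duration_range_s, event_freq_range_hz))
    if (length(r) != 2 || r[1] > r[2])
      stop("cohort_spec: ranges must be ordered (min, max)", call. = FALSE)
  if (n_subjects_per_group < 1)
    stop("cohort_spec: need at least one subject per group", call. = FALSE)
  rate_max <- max(base_event_rate) +
    max(0, rate_covariate_slope) * covariate_range[2]
  dur <- synth$duration_s
  # capacity: expected busy seconds must leave room for non-overlapping
  # placement across the nine areas
  if (rate_max * (dur / 60) * event_duration_range_s[2] > 0.5 * 9 * dur)
    stop("cohort_spec: expected event load exceeds recording capacity",
         call. = FALSE)
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 groups = groups, base_event_rate = base_event_rate,
                 rate_covariate_slope = rate_covariate_slope,
                 covariate_range = covariate_range,
                 event_duration_range_s = event_duration_range_s,
                 event_freq_range_hz = event_freq_range_hz,
                 amplitude_ratio = amplitude_ratio,
                 synth = synth, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw the ground-truth event schedule of a cohort
#'
#' The cheap half of [generate_cohort()]: samples covariates, per-subject
#' Poisson event counts and the event parameters/placements, without
#' synthesizing any EEG. Used directly for statistical calibration runs.
#'
#' @param cspec a [cohort_spec()].
#' @return List with `table` (subject_id, group, covariate, rate, true event
#'   count) and `events` (one planted event per row).
#' @export
draw_cohort_events <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  set.seed(cspec$seed)
  dur <- cspec$synth$duration_s
  rates <- rep_len(cspec$base_event_rate, length(cspec$groups))
  areas_avail <- sort(unique(
    default_montage(cspec$synth$labels)$assignment[cspec$synth$labels]))
  tab <- list(); evs <- list()
  for (gi in seq_along(cspec$groups)) {
    for (si in seq_len(cspec$n_subjects_per_group)) {
      sid <- sprintf("%s_%02d", cspec$groups[gi], si)
      cov <- stats::runif(1, cspec$covariate_range[1], cspec$covariate_range[2])
      rate <- max(0, rates[gi] + cspec$rate_covariate_slope * cov)
      n_ev <- stats::rpois(1, rate * dur / 60)
      placed <- list()
      busy <- lapply(seq_len(9), function(i) NULL)  # intervals per area
      for (k in seq_len(n_ev)) {
        ok <- FALSE
        for (attempt in seq_len(1000)) {
          area <- sample(areas_avail, 1)
          d <- stats::runif(1, cspec$event_duration_range_s[1],
                            cspec$event_duration_range_s[2])
          f <- stats::runif(1, cspec$event_freq_range_hz[1],
                            cspec$event_freq_range_hz[2])
          s <- stats::runif(1, 0, dur - d)
          iv <- busy[[area]]
          if (is.null(iv) || all(s >= iv[, 2] | s + d <= iv[, 1])) {
            busy[[area]] <- rbind(iv, c(s, s + d))
            placed[[k]] <- data.frame(
              subject_id = sid, area_id = area, start_s = s, duration_s = d,
              dominant_freq = f, amplitude_ratio = cspec$amplitude_ratio,
              stringsAsFactors = FALSE)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place event without overlap after 1000 attempts ",
               "(subject ", sid, ")", call. = FALSE)
      }
      tab[[length(tab) + 1L]] <- data.frame(
        subject_id = sid, group = cspec$groups[gi], covariate = cov,
        rate_events_per_min = rate, n_events_true = n_ev,
        stringsAsFactors = FALSE)
      if (length(placed)) evs[[length(evs) + 1L]] <- do.call(rbind, placed)
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    cbind(empty_truth_log()[, c("subject_id", "area_id", "start_s",
                                "duration_s", "dominant_freq",
                                "amplitude_ratio")])
  list(table = do.call(rbind, tab), events = events)
}

# Deterministic per-subject seed, independent of processing order.
subject_seed <- function(cohort_seed, subject_index) {
  as.integer((as.numeric(cohort_seed) * 10007 + subject_index * 7919) %%
               2147483629L)
}

#' Materialize one subject's synthetic recording
#'
#' Generates the subject's background (derived deterministic seed) and
#' plants that subject's scheduled events on all available channels of each
#' event's area.
#'
#' @param cspec a [cohort_spec()].
#' @param subject_id subject identifier present in the drawn table.
#' @param drawn result of [draw_cohort_events()] for `cspec`.
#' @return An `eeg_recording` with the truth log filled in.
#' @export
realize_subject <- function(cspec, subject_id, drawn) {
  idx <- match(subject_id, drawn$table$subject_id)
  if (is.na(idx)) stop("unknown subject '", subject_id, "'", call. = FALSE)
  sp <- cspec$synth
  sp$seed <- subject_seed(cspec$seed, idx)
  rec <- generate_background(sp)
  rec$subject_id <- subject_id
  montage <- default_montage(sp$labels)
  evs <- drawn$events[drawn$events$subject_id == subject_id, , drop = FALSE]
  for (k in seq_len(nrow(evs))) {
    chans <- intersect(sp$labels,
                       names(montage$assignment)[montage$assignment ==
                                                   evs$area_id[k]])
    rec <- plant_slow_event(rec, planted_event(
      chans, evs$start_s[k], evs$duration_s[k],
      evs$dominant_freq[k], evs$amplitude_ratio[k]))
  }
  rec
}

#' Generate a full synthetic cohort
#'
#' Eagerly materializes every subject's recording; for large cohorts prefer
#' [draw_cohort_events()] plus per-subject [realize_subject()] to bound
#' memory.
#'
#' @param cspec a [cohort_spec()].
#' @return List with `recordings` (named list of `eeg_recording`), `table`
#'   and `events` as in [draw_cohort_events()].
#' @export
generate_cohort <- function(cspec) {
  drawn <- draw_cohort_events(cspec)
  recs <- lapply(drawn$table$subject_id, function(sid)
    realize_subject(cspec, sid, drawn))
  names(recs) <- drawn$table$subject_id
  list(recordings = recs, table = drawn$table, events = drawn$events)
}
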