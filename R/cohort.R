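#' Default pipeline configuration
#'
#' Every default equals the protocol value this pipeline targets: 250 Hz,
#' 240 s recordings, 1-95 Hz band-pass, 45-55 Hz band-stop, 2 s windows
#' with 1 s overlap, MPF integration over 1-45 Hz, 6 Hz event threshold,
#' 5 s minimum duration, 2-8 Hz threshold sweep.
#'
#' @return Named list of pipeline parameters.
#' @export
default_config <- function() {
  list(bandpass = c(1, 95), bandstop = c(45, 55),
       exclude_channels = character(),
       window_s = 2, step_s = 1, mpf_band = c(1, 45), taper = "none",
       threshold_hz = 6, min_duration_s = 5, sweep_thresholds = 2:8,
       montage = NULL)
}

# Fill unspecified fields of a user config with defaults.
complete_config <- function(config = list()) {
  utils::modifyList(default_config(), config)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full single-subject pipeline
#'
#' Fixed stage order: band-pass -> band-stop -> channel exclusion ->
#' average reference -> EOG removal -> spatial averaging into 9 areas ->
#' sliding-window MPF -> event detection -> metrics and relative band
#' powers. Fully deterministic for a given recording and configuration.
#'
#' @param rec an `eeg_recording`.
#' @param config named list overriding [default_config()] entries.
#' @return A `subject_result`: list with `metrics` (per-area data frame),
#'   `events`, `mpf` (list of `mpf_series`), `band_power`, `sweep`,
#'   `subject_pct_time`, `analyzed_duration_s` and the completed `config`.
#' @export
run_subject_pipeline <- function(rec, config = list()) {
  cfg <- complete_config(config)
  pre <- with_stage("preprocess", preprocess_recording(
    rec, bandpass = cfg$bandpass, bandstop = cfg$bandstop,
    exclude = cfg$exclude_channels))
  map <- if (is.null(cfg$montage)) default_montage() else cfg$montage
  region <- with_stage("regionize", spatial_average(pre, map))
  pw <- with_stage("spectral", {
    fs <- region$fs
    starts <- seq(0, ncol(region$samples) / fs - cfg$window_s,
                  by = cfg$step_s)
    wlen <- round(cfg$window_s * fs)
    lapply(1:9, function(a) {
      if (a %in% region$missing) return(NULL)
      window_power_matrix(region$samples[a, ], fs, starts, wlen,
                          taper = cfg$taper)
    })
  })
  mpf <- with_stage("spectral", mpf_timecourse(
    region, window_s = cfg$window_s, step_s = cfg$step_s,
    band = cfg$mpf_band, taper = cfg$taper, .power = pw))
  band <- with_stage("spectral", relative_band_power(
    region, total_band = cfg$mpf_band, window_s = cfg$window_s,
    step_s = cfg$step_s, taper = cfg$taper, .power = pw))
  events <- with_stage("pswe", detect_pswe(
    mpf, threshold_hz = cfg$threshold_hz,
    min_duration_s = cfg$min_duration_s))
  dur <- duration_s(rec)
  metrics <- with_stage("pswe", subject_metrics(events, dur, band))
  sweep <- with_stage("pswe", threshold_sweep(
    mpf, thresholds = cfg$sweep_thresholds,
    min_duration_s = cfg$min_duration_s, analyzed_duration_s = dur))
  structure(list(subject_id = rec$subject_id, metrics = metrics,
                 events = events, mpf = mpf, band_power = band,
                 sweep = sweep,
                 subject_pct_time = attr(metrics, "subject_pct_time"),
                 analyzed_duration_s = dur, config = cfg),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> '%s': %d event(s), %.2f%% time in PSWE (%.0f s analyzed)\n",
              x$subject_id, nrow(x$events), x$subject_pct_time,
              x$analyzed_duration_s))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from the large-sample Student-t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman_correlation: lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman_correlation: need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_correlation: constant input, correlation undefined",
         call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Per-area nonparametric group comparison
#'
#' Kruskal-Wallis omnibus test per area; when the omnibus p-value is below
#' `alpha`, unadjusted pairwise rank-sum (Wilcoxon, normal approximation)
#' tests follow — an LSD-style policy, tagged as such in the output.
#'
#' @param df long data frame with columns `group`, `value` and optionally
#'   `area_id` (absent means one pooled stratum labelled `"all"`).
#' @param metric label recorded in the result rows.
#' @param alpha omnibus gate for the pairwise follow-up.
#' @return Data frame of test rows: `metric`, `area`, `comparison`,
#'   `statistic`, `p_value`, `method`, `correction`.
#' @export
group_compare <- function(df, metric = "n_events", alpha = 0.05) {
  if (!all(c("group", "value") %in% names(df)))
    stop("group_compare: `df` needs columns `group` and `value`",
         call. = FALSE)
  if (is.null(df$area_id)) df$area_id <- "all"
  tabs <- split(df, df$area_id)
  rows <- list()
  for (area in names(tabs)) {
    d <- tabs[[area]]
    sizes <- table(d$group)
    if (length(sizes) < 2 || any(sizes < 2))
      stop("group_compare: need >= 2 groups with >= 2 subjects each (area ",
           area, ")", call. = FALSE)
    g <- factor(d$group)
    if (stats::var(d$value) == 0) {
      kw <- list(statistic = c(chisq = 0), p.value = 1)
    } else {
      kw <- stats::kruskal.test(d$value, g)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      metric = metric, area = area, comparison = "omnibus",
      statistic = unname(kw$statistic), p_value = kw$p.value,
      method = "Kruskal-Wallis", correction = "none",
      stringsAsFactors = FALSE)
    if (kw$p.value < alpha) {
      lv <- levels(g)
      for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
        w <- suppressWarnings(stats::wilcox.test(
          d$value[g == lv[i]], d$value[g == lv[j]], exact = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, area = area,
          comparison = paste(lv[i], "vs", lv[j]),
          statistic = unname(w$statistic), p_value = w$p.value,
          method = "Wilcoxon rank-sum", correction = "unadjusted (LSD-style)",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Correlation between disease duration and event count
#'
#' Spearman correlation between a duration-like covariate and per-subject
#' event counts, either summed over all areas (`area = NULL`) or for one
#' area.
#'
#' @param table subject table with columns `subject_id` and a duration
#'   column (`disease_duration` or `covariate`).
#' @param counts per-subject event counts: either a numeric column name in
#'   `table`, or a data frame (`subject_id`, `area_id`, `n_events`).
#' @param area single area id, or `NULL` for the sum over areas.
#' @param group restrict to this group label (requires a `group` column);
#'   `NULL` uses every row.
#' @return Data frame row: `metric`, `area`, `rho`, `p_value`, `n`.
#' @export
duration_correlation <- function(table, counts = "n_events_true",
                                 area = NULL, group = NULL) {
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  durcol <- intersect(c("disease_duration", "covariate"), names(table))[1]
  if (is.na(durcol))
    stop("duration_correlation: no `disease_duration`/`covariate` column",
         call. = FALSE)
  if (is.character(counts) && length(counts) == 1) {
    cnt <- table[[counts]]
    if (is.null(cnt)) stop("duration_correlation: no column `", counts, "`",
                           call. = FALSE)
  } else {
    ev <- counts
    if (!is.null(area)) ev <- ev[ev$area_id == area, , drop = FALSE]
    agg <- stats::aggregate(n_events ~ subject_id, data = ev, FUN = sum)
    cnt <- agg$n_events[match(table$subject_id, agg$subject_id)]
    cnt[is.na(cnt)] <- 0
  }
  r <- spearman_correlation(table[[durcol]], cnt)
  data.frame(metric = "n_events", area = if (is.null(area)) "all" else area,
             rho = r$rho, p_value = r$p_value, n = r$n,
             stringsAsFactors = FALSE)
}
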