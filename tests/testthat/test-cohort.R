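test_that("spearman correlation matches the rank oracle, ties included", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_correlation(1:10, -(1:10))$rho, -1)
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)   # heavy ties
    y <- sample(1:6, 15, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(spearman_correlation(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(spearman_correlation(exp(x), y)$rho,
               spearman_correlation(x, y)$rho)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("group comparison handles degenerate and planted cases", {
  df0 <- data.frame(group = rep(c("A", "B"), each = 10), value = rep(5, 20))
  r0 <- group_compare(df0)
  expect_equal(r0$statistic[r0$comparison == "omnibus"], 0)
  expect_equal(r0$p_value[r0$comparison == "omnibus"], 1)

  set.seed(14)
  df1 <- data.frame(group = rep(c("A", "B"), each = 20),
                    value = c(rpois(20, 2), rpois(20, 12)))
  r1 <- group_compare(df1)
  expect_lt(r1$p_value[r1$comparison == "omnibus"], 0.05)
  expect_true("A vs B" %in% r1$comparison)
  expect_match(r1$correction[r1$comparison == "A vs B"], "LSD")

  # Kruskal-Wallis is invariant under monotone transforms of the metric
  df2 <- df1; df2$value <- log1p(df2$value)
  expect_equal(group_compare(df2)$p_value[1], r1$p_value[1])

  expect_error(group_compare(data.frame(group = c("A", "A", "B"),
                                        value = 1:3)),
               ">= 2 subjects")
})

test_that("duration correlation recovers the generator's link", {
  dr <- draw_cohort_events(cohort_spec(
    n_subjects_per_group = 31, groups = "PD",
    synth = synth_spec(n_channels = 9), seed = 5))
  res <- duration_correlation(dr$table, counts = "n_events_true")
  expect_equal(res$area, "all")
  ref <- suppressWarnings(stats::cor(dr$table$covariate,
                                     dr$table$n_events_true,
                                     method = "spearman"))
  expect_equal(res$rho, ref, tolerance = 1e-12)
  # per-area counts route agrees with the summed column
  counts <- stats::aggregate(cbind(n_events = start_s) ~ subject_id + area_id,
                             data = dr$events, FUN = length)
  res2 <- duration_correlation(dr$table, counts = counts)
  expect_equal(res2$rho, res$rho)
  # duplicating rows leaves rho unchanged (checked against the rank oracle)
  twice <- rbind(dr$table, dr$table)
  res3 <- duration_correlation(twice, counts = "n_events_true")
  expect_equal(res3$rho,
               oracle_spearman(twice$covariate, twice$n_events_true),
               tolerance = 1e-12)
})

test_that("subject pipeline: specificity, localized detection, determinism", {
  # clean background -> no events anywhere
  clean <- generate_background(synth_spec(n_channels = 60, duration_s = 120,
                                          seed = 31))
  res0 <- run_subject_pipeline(clean)
  expect_equal(nrow(res0$events), 0)
  expect_true(all(res0$metrics$n_events == 0))
  expect_equal(res0$subject_pct_time, 0)

  # one small-footprint (2-channel central occipital) planted event:
  # detected in its own area only (leakage through the average reference is
  # negligible for a 2/60 footprint)
  m <- default_montage()
  ch9 <- names(m$assignment)[m$assignment == 9]
  planted <- plant_slow_event(clean, planted_event(ch9, 50.2, 10, 3, 5))
  res1 <- run_subject_pipeline(planted)
  expect_gte(sum(res1$events$area_id == 9), 1)
  expect_equal(sum(res1$events$area_id != 9), 0)
  expect_true(all(res1$events$mean_mpf_hz < 6))
  # event timing matches the truth log
  expect_true(any(res1$events$start_s <= 50.2 + 5 &
                    res1$events$end_s >= 50.2 + 5))

  # determinism: identical input and config -> identical tables
  res2 <- run_subject_pipeline(planted)
  expect_identical(res1$metrics, res2$metrics)
  expect_identical(res1$events, res2$events)
  expect_identical(res1$sweep, res2$sweep)

  # stage names propagate in errors
  expect_error(run_subject_pipeline(clean, list(bandpass = c(1, 130))),
               "stage: preprocess")
})
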