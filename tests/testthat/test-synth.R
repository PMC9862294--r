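test_that("background generation honours the dimensional contract", {
  spec <- synth_spec(n_channels = 60, duration_s = 240, fs = 250, seed = 1)
  rec <- generate_background(spec)
  expect_equal(dim(rec$samples), c(60, 60000))
  expect_equal(rec$fs, 250)
  expect_setequal(unname(default_montage(rec$labels)$assignment[rec$labels]),
                  1:9)
  # determinism: same spec, same seed -> bit-identical samples
  expect_identical(generate_background(spec)$samples, rec$samples)
})

test_that("spec validation names the offending field", {
  expect_error(synth_spec(duration_s = 0), "duration_s")
  expect_error(synth_spec(n_channels = 0), "n_channels")
  expect_error(synth_spec(fs = 100), "fs")        # < 2 x highest frequency
  expect_error(synth_spec(bg_band = c(0, 95)), "bg_band")
})

test_that("flat-exponent background has MPF near the band midpoint", {
  spec <- synth_spec(n_channels = 9, duration_s = 240, spectral_exponent = 0,
                     alpha_rel_amp = 0, seed = 4)
  rs <- spatial_average(generate_background(spec))
  mpf <- mpf_timecourse(rs)
  expect_lt(abs(mean(mpf[[1]]$mpf_hz) - 23), 0.5)
})

test_that("periodogram slope matches the spectral exponent", {
  for (expo in c(0.5, 1, 1.5)) {
    spec <- synth_spec(n_channels = 1, labels = "Cz", duration_s = 240,
                       spectral_exponent = expo, alpha_rel_amp = 0, seed = 9)
    x <- generate_background(spec)$samples[1, ]
    n <- length(x)
    p <- Mod(stats::fft(x))^2
    f <- (seq_len(n) - 1) * spec$fs / n
    keep <- f >= 2 & f <= 40
    fit <- stats::lm(log(p[keep]) ~ log(f[keep]))
    expect_lt(abs(unname(stats::coef(fit)[2]) + expo), 0.3)
  }
})

test_that("planting events is additive, bounded, and logged", {
  spec <- synth_spec(n_channels = 18, labels = labels18(), duration_s = 60,
                     seed = 3)
  rec <- generate_background(spec)
  m <- default_montage()
  ch5 <- intersect(rec$labels, names(m$assignment)[m$assignment == 5])

  # amplitude zero -> identity
  ev0 <- planted_event(ch5, 10, 8, 4, 0)
  expect_equal(plant_slow_event(rec, ev0)$samples, rec$samples)

  # truth log echoes inputs
  ev <- planted_event(ch5, 10.25, 8, 4, 5)
  out <- plant_slow_event(rec, ev)
  expect_equal(out$events$start_s, 10.25)
  expect_equal(out$events$duration_s, 8)
  expect_equal(out$events$dominant_freq, 4)
  expect_equal(out$events$area_id, 5L)
  # samples outside the event untouched
  pre <- 1:(10 * spec$fs)
  expect_equal(out$samples[, pre], rec$samples[, pre])

  # all fully-inside windows are sub-threshold after averaging
  rs <- spatial_average(out)
  mpf <- mpf_timecourse(rs)[[5]]
  inside <- mpf$times_s >= 11 & mpf$times_s + 2 <= 18.25
  expect_true(all(mpf$mpf_hz[inside] < 6))

  expect_error(plant_slow_event(rec, planted_event(ch5, 55, 10, 4, 5)),
               "exceeds")
  expect_error(plant_slow_event(rec, planted_event("Zz9", 1, 5, 4, 5)),
               "unknown channel")
  expect_error(planted_event(ch5, -1, 5, 4, 5), "start_s")
})

test_that("cohort drawing matches its rate model and bookkeeping", {
  cs <- cohort_spec(n_subjects_per_group = 4, groups = c("PD", "HC"),
                    synth = synth_spec(n_channels = 9, duration_s = 120),
                    seed = 21)
  dr <- draw_cohort_events(cs)
  expect_equal(nrow(dr$table), 8)            # n per group x |groups|
  expect_setequal(unique(dr$table$group), c("PD", "HC"))
  expect_equal(sum(dr$table$n_events_true), nrow(dr$events))
  # determinism
  dr2 <- draw_cohort_events(cs)
  expect_identical(dr$table, dr2$table)
  expect_identical(dr$events, dr2$events)
  # events fit the recording and never overlap within an area
  with(dr$events, expect_true(all(start_s >= 0 & start_s + duration_s <= 120)))
  for (sid in unique(dr$events$subject_id)) {
    for (a in unique(dr$events$area_id)) {
      e <- dr$events[dr$events$subject_id == sid & dr$events$area_id == a, ]
      if (nrow(e) > 1) {
        o <- order(e$start_s)
        expect_true(all(e$start_s[o][-1] >=
                          (e$start_s + e$duration_s)[o][-nrow(e)]))
      }
    }
  }
  # capacity validation
  expect_error(cohort_spec(base_event_rate = 500,
                           synth = synth_spec(n_channels = 9)),
               "capacity")
})

test_that("zero slope decouples counts from the covariate; positive slope links them", {
  rhos0 <- rhos1 <- numeric(20)
  for (i in 1:20) {
    d0 <- draw_cohort_events(cohort_spec(
      n_subjects_per_group = 31, groups = "PD", base_event_rate = 1,
      rate_covariate_slope = 0,
      synth = synth_spec(n_channels = 9), seed = 100 + i))
    rhos0[i] <- suppressWarnings(stats::cor(d0$table$covariate,
                                            d0$table$n_events_true,
                                            method = "spearman"))
    d1 <- draw_cohort_events(cohort_spec(
      n_subjects_per_group = 31, groups = "PD",
      synth = synth_spec(n_channels = 9), seed = 100 + i))
    rhos1[i] <- suppressWarnings(stats::cor(d1$table$covariate,
                                            d1$table$n_events_true,
                                            method = "spearman"))
  }
  expect_lt(mean(abs(rhos0)), 0.25)
  expect_gte(mean(rhos1 > 0), 0.9)
})
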