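test_that("psd_window has the stated resolution and Parseval holds", {
  fs <- 250
  t <- (0:499) / fs
  sp <- psd_window(sin(2 * pi * 10 * t), fs)
  expect_equal(sp$freqs, seq(0, 125, by = 0.5))       # 0.5 Hz bins
  expect_equal(sp$freqs[which.max(sp$power)], 10)     # line at 10 Hz
  x <- rnorm(500)
  sp2 <- psd_window(x, fs, detrend = FALSE)
  expect_equal(sum(sp2$power), mean(x^2), tolerance = 1e-6)
  # Hann taper keeps the normalization
  sp3 <- psd_window(x, fs, detrend = FALSE, taper = "hann")
  expect_equal(sp3$freqs, sp2$freqs)
  expect_error(psd_window(x[1:499], fs), "even")
})

test_that("median power frequency matches analytic cases and the oracle", {
  f <- seq(0, 125, by = 0.5)
  # single line at 4 Hz
  p <- numeric(length(f)); p[f == 4] <- 1
  expect_lt(abs(median_power_frequency(list(freqs = f, power = p)) - 4), 0.5)
  # flat band
  expect_lt(abs(median_power_frequency(list(freqs = f,
                                            power = rep(1, length(f)))) - 23),
            0.5)
  # two equal lines at 3 and 9 Hz: the cumulative sum reaches exactly half
  # at the 3 Hz bin, and ties resolve to the lower frequency
  p2 <- numeric(length(f)); p2[f %in% c(3, 9)] <- 1
  got <- median_power_frequency(list(freqs = f, power = p2))
  expect_gte(got, 3); expect_lt(got, 9)
  expect_identical(got, oracle_mpf(f, p2, 1, 45))

  # scale invariance
  set.seed(1)
  pr <- runif(length(f))
  expect_equal(median_power_frequency(list(freqs = f, power = pr)),
               median_power_frequency(list(freqs = f, power = 1e6 * pr)))
  expect_error(median_power_frequency(list(freqs = f, power = 0 * f)),
               "undefined MPF")
  expect_error(median_power_frequency(list(freqs = f, power = pr), 1, 300),
               "outside the spectrum")
})

test_that("moving power mass downward never increases MPF", {
  f <- seq(0, 125, by = 0.5)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(length(f))
    m0 <- median_power_frequency(list(freqs = f, power = p))
    hi <- sample(which(f > 20 & f <= 45), 1)
    lo <- sample(which(f >= 1 & f < 10), 1)
    q <- p
    moved <- 0.8 * q[hi]
    q[hi] <- q[hi] - moved; q[lo] <- q[lo] + moved
    expect_lte(median_power_frequency(list(freqs = f, power = q)), m0)
  }
})

test_that("mpf_timecourse windows agree with single-window oracle calls", {
  set.seed(5)
  fs <- 250; dur <- 60
  labs <- default_labels(9)
  rec <- new_recording(matrix(rnorm(9 * fs * dur), 9), fs, labs)
  rs <- spatial_average(rec)
  mpf <- mpf_timecourse(rs)
  expect_length(mpf, 9)
  expect_length(mpf[[1]]$mpf_hz, dur - 2 + 1)     # (60 - 2)/1 + 1 windows
  expect_equal(mpf[[1]]$times_s, 0:(dur - 2))
  for (i in c(1, 17, 58)) {
    seg <- rs$samples[3, (i - 1) * fs + 1:(2 * fs)]
    expect_equal(mpf[[3]]$mpf_hz[i],
                 median_power_frequency(psd_window(seg, fs), 1, 45))
  }
  # stationary (periodic) signal -> constant MPF series
  t <- (0:(fs * dur - 1)) / fs
  recs <- new_recording(matrix(rep(sin(2 * pi * 7 * t), each = 9), 9), fs, labs)
  mpfs <- mpf_timecourse(spatial_average(recs))
  expect_lt(stats::sd(mpfs[[1]]$mpf_hz), 0.5)
  expect_error(mpf_timecourse(spatial_average(
    new_recording(matrix(rnorm(9 * fs), 9), fs, labs))), "shorter")
})

test_that("relative band power matches single-line and flat spectra", {
  fs <- 250; dur <- 40
  t <- (0:(fs * dur - 1)) / fs
  labs <- default_labels(9)
  mk <- function(freq) spatial_average(new_recording(
    matrix(rep(sin(2 * pi * freq * t), each = 9), 9), fs, labs))
  bp10 <- relative_band_power(mk(10))
  expect_true(all(bp10$alpha >= 0.99))
  bp3 <- relative_band_power(mk(3))
  expect_true(all(bp3$delta >= 0.99))
  expect_true(all(bp3$theta <= 0.01))
  # values live in [0,1] and the four bands cannot exceed the total
  sums <- rowSums(bp10[, c("delta", "theta", "alpha", "beta")])
  expect_true(all(sums <= 1 + 1e-12))

  # flat-spectrum background: proportions of a flat band (half-open bins)
  flat <- generate_background(synth_spec(n_channels = 9, duration_s = 120,
                                         spectral_exponent = 0,
                                         alpha_rel_amp = 0, seed = 2))
  bpf <- relative_band_power(spatial_average(flat))
  expect_equal(mean(bpf$delta), 4 / 44, tolerance = 0.01 / (4 / 44))
  expect_equal(mean(bpf$theta), 3 / 44, tolerance = 0.01 / (3 / 44))
  expect_equal(mean(bpf$alpha), 4 / 44, tolerance = 0.01 / (4 / 44))
  expect_equal(mean(bpf$beta), 8 / 44, tolerance = 0.01 / (8 / 44))
})

test_that("Welch average of identical windows equals one window", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 12 * t)
  labs <- default_labels(9)
  rs <- spatial_average(new_recording(matrix(rep(x, each = 9), 9), fs, labs))
  pm <- pswer:::window_power_matrix(rs$samples[1, ], fs, 0:18, 2 * fs)
  one <- psd_window(rs$samples[1, 1:(2 * fs)], fs)
  expect_equal(rowMeans(pm$power), one$power, tolerance = 1e-10)
})
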