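# A short continuous recording with known content for filter checks.
make_raw <- function(signal_fun, fs = 2048, dur = 6, n_ch = 2,
                     events = tibble::tibble(sentence = "s01",
                                             sample = round(fs * 2))) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- signal_fun(t)
  raw_recording(matrix(rep(x, n_ch), ncol = n_ch), fs, events,
                positions = sensor_layout(n_ch))
}

mid_rms <- function(x, fs) {
  n <- length(x)
  sd(x[round(n * 0.25):round(n * 0.75)])
}

test_that("broadband filtering attenuates drift, passes the band, and is zero-phase", {
  raw01 <- make_raw(function(t) sin(2 * pi * 0.1 * t))
  f01 <- bandlimit_raw(raw01)
  expect_lt(20 * log10(mid_rms(f01$data[, 1], 2048) /
                         mid_rms(raw01$data[, 1], 2048)), -20)
  raw10 <- make_raw(function(t) sin(2 * pi * 10 * t))
  f10 <- bandlimit_raw(raw10)
  expect_lt(abs(20 * log10(mid_rms(f10$data[, 1], 2048) /
                             mid_rms(raw10$data[, 1], 2048))), 1)
  # symmetric Gaussian pulse keeps its peak sample
  rawp <- make_raw(function(t) exp(-0.5 * ((t - 3) / 0.05)^2))
  fp <- bandlimit_raw(rawp)
  expect_identical(which.max(fp$data[, 1]), which.max(rawp$data[, 1]))
  low_rate <- raw_recording(matrix(0, 600, 2), 100,
                            tibble::tibble(sentence = "a", sample = 300))
  expect_error(bandlimit_raw(low_rate), "at least 512")
})

test_that("resampling preserves duration and passband amplitude", {
  raw <- make_raw(function(t) sin(2 * pi * 4 * t))
  r256 <- resample_eeg(raw, 256)
  expect_equal(nrow(r256$data), 6 * 256, tolerance = 1)
  expect_lt(abs(mid_rms(r256$data[, 1], 256) / mid_rms(raw$data[, 1], 2048) - 1),
            0.02)
  expect_equal(r256$events$sample, round((raw$events$sample - 1) / 8) + 1)
  # 256 -> 128 halves the sample count (within one sample)
  ts <- make_trial_set(array(rnorm(2 * 2 * 768), c(2, 2, 768)), fs = 256)
  half <- resample_eeg(ts, 128)
  expect_lte(abs(dim(half$data)[3] - 384), 1)
  # content above the new Nyquist is suppressed, not aliased: a 200 Hz
  # tone would fold to 56 Hz after decimation to 256 Hz
  tt <- seq(0, 4 - 1 / 2048, by = 1 / 2048)
  two_tone <- raw_recording(matrix(sin(2 * pi * 40 * tt) +
                                     sin(2 * pi * 200 * tt), ncol = 1), 2048,
                            tibble::tibble(sentence = "a", sample = 1000))
  dt <- resample_eeg(two_tone, 256)
  t_out <- (seq_len(nrow(dt$data)) - 1) / 256
  amp_at <- function(f) 2 * Mod(mean(dt$data[, 1] * exp(-2i * pi * f * t_out)))
  expect_gt(amp_at(40), 0.95)
  expect_lt(20 * log10(amp_at(56) / amp_at(40)), -30)
  expect_error(resample_eeg(raw, 2048 / pi), "rational")
  expect_error(resample_eeg(raw, 4096), "below")
})

test_that("epoching aligns trials to onsets and logs edge drops", {
  fs <- 256
  n <- fs * 40
  dat <- matrix(0, n, 2)
  ev <- round(seq(fs * 1, n - fs * 3, length.out = 10))
  dat[ev, 1] <- 5  # impulse planted at each onset
  raw <- raw_recording(dat, fs, tibble::tibble(sentence = "s01", sample = ev))
  tr <- epoch_recording(raw)[["s01"]]
  expect_identical(dim(tr$data)[1], 10L)
  on <- speechtrack:::onset_index(tr)
  expect_true(all(tr$data[, 1, on] == 5))
  expect_equal(speechtrack:::ts_time(tr)[on], 0)
  # an event at the very start cannot be epoched and is logged
  raw_edge <- raw_recording(dat, fs,
                            tibble::tibble(sentence = "s01", sample = c(1L, ev)))
  tr2 <- epoch_recording(raw_edge)[["s01"]]
  expect_identical(dim(tr2$data)[1], 10L)
  expect_identical(tr2$log$dropped, 1L)
})

test_that("amplitude rejection uses a strict 200 uV boundary and full logging", {
  dat <- array(0, c(3, 2, 100))
  dat[1, 1, 50] <- 250
  dat[2, 2, 10] <- 200   # exactly at threshold: kept
  ts <- make_trial_set(dat, fs = 128, pre_s = 0)
  out <- reject_amplitude(ts)
  expect_identical(dim(out$data)[1], 2L)
  expect_identical(out$log$dropped, 1L)
  expect_identical(dim(out$data)[1] + length(out$log$dropped), 3L)
  # all-zero trials are kept; rejecting everything is an error
  expect_identical(dim(reject_amplitude(make_trial_set(array(0, c(2, 2, 10)),
                                                       pre_s = 0))$data)[1], 2L)
  loud <- make_trial_set(array(300, c(2, 2, 10)), pre_s = 0, sentence = "s07")
  expect_error(reject_amplitude(loud), "s07")
})

test_that("channel interpolation rebuilds a bad channel from its neighbors", {
  set.seed(4)
  n_ch <- 8
  sig <- sin(2 * pi * 3 * seq(0, 2, length.out = 256))
  dat <- array(rep(sig, each = 2 * n_ch), c(2, n_ch, 256))
  dat[, 4, ] <- rnorm(2 * 256)  # corrupt one channel
  ts <- make_trial_set(dat, fs = 128, pre_s = 0,
                       positions = sensor_layout(n_ch))
  fixed <- interpolate_channels(ts, "ch04")
  expect_gt(cor(fixed$data[1, 4, ], sig), 0.99)
  expect_identical(fixed$data[, -4, ], dat[, -4, ])  # good channels untouched
  expect_identical(fixed$log$interpolated, "ch04")
  expect_identical(interpolate_channels(ts, character(0)), ts)
  expect_error(interpolate_channels(ts, ts$channels), "25%")
  expect_error(interpolate_channels(ts, "ch99"), "not found")
})

test_that("final band-pass keeps 8 Hz, suppresses 30 Hz, zero phase", {
  fs <- 256
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  mk <- function(x) {
    arr <- array(0, c(1, 2, length(x)))
    arr[1, 1, ] <- x
    arr[1, 2, ] <- x
    make_trial_set(arr, fs = fs, pre_s = 0)
  }
  g8 <- final_bandpass(mk(sin(2 * pi * 8 * t)))
  expect_lt(abs(20 * log10(mid_rms(g8$data[1, 1, ], fs) / (1 / sqrt(2)))), 1)
  g30 <- final_bandpass(mk(sin(2 * pi * 30 * t)))
  expect_lt(20 * log10(mid_rms(g30$data[1, 1, ], fs) / (1 / sqrt(2))), -20)
  pulse <- mk(exp(-0.5 * ((t - 3) / 0.1)^2) * sin(2 * pi * 6 * t))
  gp <- final_bandpass(pulse)
  expect_lt(abs(which.max(abs(gp$data[1, 1, ])) -
                  which.max(abs(pulse$data[1, 1, ]))), 3)
})

test_that("the full chain preserves 1-15 Hz content of a clean signal", {
  fs <- 512
  dur <- 30
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- sin(2 * pi * 3 * t) + 0.7 * sin(2 * pi * 8 * t + 1) +
    0.5 * sin(2 * pi * 12 * t + 2)
  ev <- round(seq(fs * 1, fs * (dur - 3.5), length.out = 6))
  raw <- raw_recording(matrix(rep(sig, 4), ncol = 4), fs,
                       tibble::tibble(sentence = "s01", sample = ev),
                       positions = sensor_layout(4))
  out <- preprocess_raw(raw)[["s01"]]
  expect_equal(out$fs, 128)
  expect_identical(dim(out$data)[1], 6L)
  # compare each epoch to the ground-truth signal segment at 128 Hz
  for (i in c(1, 4)) {
    t_ep <- (ev[i] - 1) / fs + speechtrack:::ts_time(out)
    truth <- sin(2 * pi * 3 * t_ep) + 0.7 * sin(2 * pi * 8 * t_ep + 1) +
      0.5 * sin(2 * pi * 12 * t_ep + 2)
    expect_gt(cor(out$data[i, 1, ], truth), 0.98)
  }
})

test_that("artifact hook passes data through and records the skip", {
  ts <- make_trial_set(array(rnorm(40), c(2, 2, 10)))
  out <- remove_artifacts(ts)
  expect_identical(out$data, ts$data)
  expect_match(out$log$artifact_removal, "skipped")
  expect_error(remove_artifacts(ts, method = "ica"), "pass-through")
})
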