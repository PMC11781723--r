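test_that("a pure sinusoid yields peaks at its analytic extrema", {
  fs <- 60
  t <- (0:(10 * fs - 1)) / fs
  x <- ppg_signal(sin(2 * pi * t), fs)
  pk <- detect_events(x, "peak")
  expect_equal(nrow(pk), 10)
  expect_equal(pk$time, 0.25 + 0:9, tolerance = 1 / fs)
})

test_that("valleys of a signal are peaks of its negation", {
  pair <- generate_ppg_pair(signal_spec(fs = 60, duration_s = 20, seed = 8))
  x <- bandpass(pair$face)
  neg <- ppg_signal(-x$value, 60)
  expect_equal(detect_events(x, "valley")$time,
               detect_events(neg, "peak")$time)
})

test_that("every true beat is recovered within one sample on clean input", {
  pair <- generate_ppg_pair(signal_spec(fs = 60, duration_s = 30,
                                        heart_rate_bpm = 62, seed = 21))
  pk <- detect_events(bandpass(pair$face), "peak")
  for (b in pair$beats) {
    expect_lt(min(abs(pk$time - b)), 1 / 60 + 1e-9)
  }
})

test_that("too few events raises a quality error", {
  x <- ppg_signal(sin(2 * pi * (0:179) / 60), 60)  # 3 s: 3 peaks
  expect_error(detect_events(x, "peak"), "too short/noisy")
})

test_that("pairing matches shifted trains one-to-one", {
  f <- make_events(seq(0.5, 10, by = 1))
  h <- make_events(seq(0.5, 10, by = 1) + 0.033, site = "hand")
  pr <- pair_events(f, h, max_lag = 0.4)
  expect_equal(nrow(pr$pairs), 10)
  expect_equal(pr$pairs$dt, rep(-0.033, 10))
  expect_equal(pr$unmatched_face, 0)
  expect_equal(pr$unmatched_hand, 0)
})

test_that("a missing beat leaves one unmatched event", {
  f_times <- seq(0.5, 10, by = 1)
  f <- make_events(f_times)
  h <- make_events(f_times[-7] + 0.03, site = "hand")
  pr <- pair_events(f, h, max_lag = 0.4)
  expect_equal(nrow(pr$pairs), 9)
  expect_equal(pr$unmatched_face, 1)
  expect_false((f_times[7]) %in% pr$pairs$t_face)
})

test_that("trains offset beyond max_lag produce no pairs and a downstream error", {
  f <- make_events(seq(0.5, 10, by = 1))
  h <- make_events(seq(0.5, 10, by = 1) + 0.45, site = "hand")
  pr <- pair_events(f, h, max_lag = 0.2)
  expect_equal(nrow(pr$pairs), 0)
  expect_error(mean_transit_time(pr), "too short/noisy")
  expect_error(pair_events(f, make_events(numeric(0))), "empty event train")
})

test_that("mean transit time is the arithmetic mean of absolute gaps", {
  f <- make_events(1:6)
  h <- make_events(1:6 + c(0.02, 0.03, 0.04, 0.02, 0.03, 0.04), site = "hand")
  pr <- pair_events(f, h, max_lag = 0.3)
  expect_equal(mean_transit_time(pr), 0.03)
  h2 <- make_events(1:6 + 0.033, site = "hand")
  expect_equal(mean_transit_time(pair_events(f, h2, max_lag = 0.3)), 0.033)
  expect_error(mean_transit_time(pair_events(make_events(1:3),
                                             make_events(1:3 + 0.01),
                                             max_lag = 0.3)),
               "too short/noisy")
})

test_that("pure sample delays are recovered within one sample", {
  fs <- 60
  for (k in 1:10) {
    pair <- generate_ppg_pair(signal_spec(fs = fs, duration_s = 25,
                                          transit_delay_s = k / fs,
                                          seed = 40 + k))
    tt <- compute_transit_times(bandpass(pair$face), bandpass(pair$hand))
    expect_lt(abs(tt$ptt_s - k / fs), 1 / fs)
    expect_lt(abs(tt$ptt_d - k / fs), 1 / fs)
  }
})

test_that("zero shift is flagged as undefined rather than failing", {
  pair <- generate_ppg_pair(signal_spec(fs = 60, duration_s = 20,
                                        transit_delay_s = 0, seed = 12))
  tt <- compute_transit_times(bandpass(pair$face), bandpass(pair$hand))
  expect_equal(tt$ptt_s, 0, tolerance = 1e-6)
  expect_true(any(grepl("zero transit time", tt$qc)))
})

test_that("distinct peak and valley delays are measured independently", {
  pair <- generate_ppg_pair(signal_spec(fs = 60, duration_s = 30,
                                        peak_delay_s = 0.03,
                                        valley_delay_s = 0.05, seed = 13))
  tt <- compute_transit_times(bandpass(pair$face), bandpass(pair$hand))
  expect_lt(abs(tt$ptt_s - 0.03), 1 / 60)
  expect_lt(abs(tt$ptt_d - 0.05), 1 / 60)
  expect_gt(tt$ptt_d, tt$ptt_s)
})

test_that("transit time is symmetric under site exchange and common delay", {
  pair <- generate_ppg_pair(signal_spec(fs = 60, duration_s = 25,
                                        transit_delay_s = 3 / 60, seed = 14))
  f <- bandpass(pair$face); h <- bandpass(pair$hand)
  tt <- compute_transit_times(f, h)
  swapped <- compute_transit_times(h, f)
  expect_equal(swapped$ptt_s, tt$ptt_s, tolerance = 1e-12)
  # advancing both signals by the same whole number of samples changes nothing
  m <- 30
  f2 <- ppg_signal(f$value[-(1:m)], 60, "face")
  h2 <- ppg_signal(h$value[-(1:m)], 60, "hand")
  tt2 <- compute_transit_times(f2, h2)
  expect_equal(tt2$ptt_s, tt$ptt_s, tolerance = 2 / 60)
})
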