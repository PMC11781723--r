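test_that("spatial averaging reproduces exact channel means", {
  video <- uniform_video(3, rgb = c(120, 80, 60))
  roi <- construct_roi(cbind(c(10, 30, 30, 10), c(10, 10, 30, 30)),
                       "forehead", 1:4)
  tr <- mean_rgb_trace(video, roi, site = "face")
  expect_equal(tr$r, rep(120, 3))
  expect_equal(tr$g, rep(80, 3))
  expect_equal(tr$b, rep(60, 3))

  # left half (0,0,0), right half (2,4,6) inside a centred ROI
  f <- array(0, dim = c(40, 40, 3))
  for (c in 1:3) f[, 22:40, c] <- 2 * c  # value region starts at x = 21
  v <- vbp_video(list(f), fps = 60)
  roi2 <- construct_roi(cbind(c(10.5, 30.5, 30.5, 10.5), c(10, 10, 30, 30)),
                        "forehead", 1:4)
  tr2 <- mean_rgb_trace(v, roi2, frame_indices = 0L)
  expect_equal(c(tr2$r, tr2$g, tr2$b), c(1, 2, 3))
})

test_that("a single-pixel ROI returns that pixel's values", {
  f <- array(7, dim = c(20, 20, 3))
  f[6, 11, ] <- c(200, 100, 50)  # pixel centre x = 10, y = 5
  v <- vbp_video(list(f), fps = 60)
  roi <- construct_roi(cbind(c(9.6, 10.4, 10.4, 9.6), c(4.6, 4.6, 5.4, 5.4)),
                       "palm", 1:4)
  tr <- mean_rgb_trace(v, roi, frame_indices = 0L, site = "hand")
  expect_equal(c(tr$r, tr$g, tr$b), c(200, 100, 50))
})

test_that("chrominance extraction recovers the pulse frequency", {
  spec <- signal_spec(fs = 60, duration_s = 30, heart_rate_bpm = 72, seed = 5)
  st <- generate_skin_trace(spec)
  ppg <- chrom_extract(st$trace)
  expect_equal(dominant_freq(ppg$value, 60), 1.2, tolerance = 0.05)
})

test_that("chrominance extraction suppresses common-mode illumination drift", {
  spec <- signal_spec(fs = 60, duration_s = 30, heart_rate_bpm = 72,
                      drift_amplitude = 0.10, drift_freq_hz = 0.05, seed = 5)
  st <- generate_skin_trace(spec)
  ppg <- chrom_extract(st$trace)
  expect_equal(dominant_freq(ppg$value, 60), 1.2, tolerance = 0.05)
  # drift-to-pulse power ratio must collapse relative to the raw channel
  raw_ratio <- band_power(st$trace$g, 60, 0.05, 0.04) /
    band_power(st$trace$g, 60, 1.2, 0.1)
  out_ratio <- band_power(ppg$value, 60, 0.05, 0.04) /
    band_power(ppg$value, 60, 1.2, 0.1)
  expect_lt(out_ratio, raw_ratio / 100)
})

test_that("chrominance output is invariant to common channel scaling", {
  st <- generate_skin_trace(signal_spec(fs = 60, duration_s = 20, seed = 9))
  ppg <- chrom_extract(st$trace)
  tr2 <- st$trace
  tr2$r <- tr2$r * 3.7; tr2$g <- tr2$g * 3.7; tr2$b <- tr2$b * 3.7
  ppg2 <- chrom_extract(tr2)
  expect_lt(max(abs(ppg2$value - ppg$value)) / sd(ppg$value), 1e-6)
})

test_that("a constant trace yields a zero signal with a warning, not an error", {
  tr <- mean_rgb_trace(uniform_video(200), construct_roi(
    cbind(c(10, 30, 30, 10), c(10, 10, 30, 30)), "forehead", 1:4))
  expect_warning(ppg <- chrom_extract(tr), "no pulsatile component")
  expect_true(all(ppg$value == 0))
})

test_that("signal extraction is deterministic", {
  s1 <- generate_skin_trace(signal_spec(fs = 60, duration_s = 10, seed = 33))
  s2 <- generate_skin_trace(signal_spec(fs = 60, duration_s = 10, seed = 33))
  expect_identical(chrom_extract(s1$trace)$value, chrom_extract(s2$trace)$value)
})

test_that("band-pass gains match the designed filter's magnitude response", {
  fs <- 60
  t <- (0:(fs * 30 - 1)) / fs
  # oracle: squared magnitude response (forward-backward application),
  # evaluated directly from the transfer-function polynomials
  gain <- function(f_hz) {
    flt <- signal::butter(2, c(0.25, 15) / (fs / 2), type = "pass")
    z <- exp(-1i * 2 * pi * f_hz / fs)
    h <- sum(flt$b * z^(seq_along(flt$b) - 1)) /
      sum(flt$a * z^(seq_along(flt$a) - 1))
    Mod(h)^2
  }
  x <- ppg_signal(sin(2 * pi * 1 * t), fs)
  y <- bandpass(x)
  core <- (5 * fs):(25 * fs)  # avoid edge transients
  measured <- sqrt(mean(y$value[core]^2)) / sqrt(0.5)
  expect_equal(measured, as.numeric(gain(1)), tolerance = 0.01)
  # pass-band: 1 Hz within 1% of unit amplitude
  expect_gt(measured, 0.99)
  # stop-band: 0.05 Hz attenuated below 10%
  x2 <- ppg_signal(sin(2 * pi * 0.05 * t), fs)
  y2 <- bandpass(x2)
  expect_lt(max(abs(y2$value[core])), 0.1)
})

test_that("band-pass output is zero-mean and rejects DC", {
  x <- ppg_signal(rep(5, 600), 60)
  y <- bandpass(x)
  expect_lt(max(abs(y$value)), 1e-8)
  st <- generate_skin_trace(signal_spec(fs = 60, duration_s = 20, seed = 2))
  y2 <- bandpass(chrom_extract(st$trace))
  expect_lt(abs(mean(y2$value)), 1e-6 * sd(y2$value))
})

test_that("infeasible cutoffs are clipped with a warning or rejected", {
  x <- ppg_signal(sin(2 * pi * (0:299) / 30), 30)
  expect_warning(bandpass(x, high = 15), "clipped")
  expect_error(bandpass(x, high = 15, auto_clip = FALSE), "Nyquist")
})

test_that("zero-phase filtering does not displace pulse peaks", {
  pair <- generate_ppg_pair(signal_spec(fs = 60, duration_s = 20,
                                        transit_delay_s = 0, seed = 4))
  raw_pk <- detect_events(pair$face, "peak", refine = FALSE)
  flt_pk <- detect_events(bandpass(pair$face), "peak", refine = FALSE)
  common <- min(nrow(raw_pk), nrow(flt_pk))
  shift <- vapply(flt_pk$index[seq_len(common)], function(i) {
    min(abs(raw_pk$index - i))
  }, numeric(1))
  expect_true(all(shift < 1 + 1e-9))
})
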