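# Shared fixture builders. Everything is generated in code; no stored data.

# A 3x4 grid of face points plus a 2x2 hand patch, all inside a W x H frame.
grid_landmarks <- function(n_frames = 5, offset = c(0, 0), scale = 1,
                           valid = rep(TRUE, n_frames)) {
  face <- scale * cbind(rep(c(10, 20, 30, 40), 3),
                        rep(c(10, 20, 30), each = 4)) +
    matrix(offset, nrow = 12, ncol = 2, byrow = TRUE)
  hand <- scale * cbind(c(60, 70, 70, 60), c(30, 30, 40, 40)) +
    matrix(offset, nrow = 4, ncol = 2, byrow = TRUE)
  tibble::tibble(
    frame_index = seq_len(n_frames) - 1L,
    face = rep(list(face), n_frames),
    hand = rep(list(hand), n_frames),
    valid = valid)
}

# Uniform-colour clip.
uniform_video <- function(n_frames = 5, rgb = c(120, 80, 60),
                          width = 100, height = 60, fps = 60) {
  f <- array(0, dim = c(height, width, 3))
  for (c in 1:3) f[, , c] <- rgb[c]
  vbp_video(rep(list(f), n_frames), fps = fps)
}

# Event train with given times (seconds).
make_events <- function(times, kind = "peak", fs = 60, site = "face") {
  structure(
    tibble::tibble(kind = kind, index = round(times * fs) + 1L, time = times),
    fs = fs, site = site,
    class = c("vbp_events", class(tibble::tibble())))
}

# Single-sided FFT band power of x around f0 (+/- half_bw), fs in Hz.
band_power <- function(x, fs, f0, half_bw = 0.1) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs <= fs / 2
  sel <- keep & abs(freqs - f0) <= half_bw
  sum(sp[sel])
}

# Dominant frequency of x between lo and hi Hz.
dominant_freq <- function(x, fs, lo = 0.5, hi = 5) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= lo & freqs <= hi
  freqs[sel][which.max(sp[sel])]
}

table3_means <- data.frame(height_cm = 158.1, age_years = 40.35,
                           weight_kg = 63.80)

# Pipeline config sized for the small synthetic clips (the resolution floor
# is a capture requirement for real cameras, not for rendered fixtures).
synthetic_config <- function(variant = "demographic", ...) {
  vbp_config(variant, min_width = 64, min_height = 48, ...)
}
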