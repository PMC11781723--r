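#' Specification for synthetic pulse-pair generation
#'
#' Collects every knob of the paired-pulse generator in one validated
#' object. All randomness (beat jitter, additive noise) is a pure function
#' of `seed`.
#'
#' @param fs sampling rate, Hz (>= 30).
#' @param duration_s clip length, seconds.
#' @param heart_rate_bpm mean heart rate.
#' @param transit_delay_s face-to-hand transit delay, seconds (must be less
#'   than one beat period).
#' @param peak_delay_s,valley_delay_s optional distinct delays for peaks and
#'   valleys (asymmetric transit); when both are given they override
#'   `transit_delay_s`.
#' @param noise_sd additive Gaussian noise standard deviation, in units of
#'   the unit-amplitude pulse waveform.
#' @param drift_amplitude,drift_freq_hz common-mode illumination drift
#'   (multiplicative sinusoid) used by the skin-trace/video generators.
#' @param jitter_cv coefficient of variation of the lognormal beat-interval
#'   jitter (default 3%).
#' @param seed integer seed fixing all randomness.
#' @return A `vbp_signal_spec` list.
#' @export
signal_spec <- function(fs = 60, duration_s = 30, heart_rate_bpm = 62,
                        transit_delay_s = 2 / 60, peak_delay_s = NULL,
                        valley_delay_s = NULL, noise_sd = 0,
                        drift_amplitude = 0, drift_freq_hz = 0.05,
                        jitter_cv = 0.03, seed = 1L) {
  stopifnot(fs >= 30, duration_s > 0, heart_rate_bpm > 0, noise_sd >= 0,
            jitter_cv >= 0)
  period <- 60 / heart_rate_bpm
  delays <- c(transit_delay_s, peak_delay_s, valley_delay_s)
  if (any(abs(delays) >= period)) {
    abort("transit delays must be shorter than one beat period",
          class = "videobp_input_error")
  }
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm,
                 transit_delay_s = transit_delay_s,
                 peak_delay_s = peak_delay_s, valley_delay_s = valley_delay_s,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_freq_hz = drift_freq_hz, jitter_cv = jitter_cv,
                 seed = as.integer(seed)),
            class = "vbp_signal_spec")
}

# Continuous PPG surrogate: per beat, a unit-amplitude systolic Gaussian
# plus a dicrotic bump 0.35 s later (0.35 amplitude). A standard two-Gaussian
# pulse shape: sharp primary wave, slower composite decay. The dicrotic
# width is chosen so its tail runs into the next beat's upstroke, giving a
# V-shaped diastolic foot (a flat inter-beat plateau would make valley
# timing ill-defined, unlike real pulse waveforms).
eval_pulse <- function(t, beats, sigma1 = 0.08, amp2 = 0.35, mu2 = 0.35,
                       sigma2 = 0.18) {
  out <- numeric(length(t))
  for (b in beats) {
    dt <- t - b
    near <- abs(dt) < 1.2
    if (any(near)) {
      d <- dt[near]
      out[near] <- out[near] + exp(-d^2 / (2 * sigma1^2)) +
        amp2 * exp(-(d - mu2)^2 / (2 * sigma2^2))
    }
  }
  out
}

draw_beats <- function(spec) {
  T0 <- 60 / spec$heart_rate_bpm
  if (spec$jitter_cv > 0) {
    sdlog <- sqrt(log(1 + spec$jitter_cv^2))
    meanlog <- log(T0) - sdlog^2 / 2
    n <- ceiling((spec$duration_s + 3) / T0 * 1.5) + 3L
    intervals <- stats::rlnorm(n, meanlog, sdlog)
  } else {
    intervals <- rep(T0, ceiling((spec$duration_s + 3) / T0) + 3L)
  }
  beats <- 0.4 + cumsum(c(0, intervals))
  beats[beats < spec$duration_s + 1.5]
}

# True valley (waveform minimum) between each pair of consecutive beats.
true_valleys <- function(beats) {
  vapply(seq_len(length(beats) - 1L), function(i) {
    stats::optimize(function(t) eval_pulse(t, beats),
                    lower = beats[i] + 0.05, upper = beats[i + 1L] - 0.05)$minimum
  }, numeric(1))
}

#' Generate a paired face/hand pulse-signal pair with known transit delay
#'
#' The face signal is a jittered train of two-Gaussian pulse waveforms; the
#' hand signal is the same underlying waveform delayed by
#' `transit_delay_s`. When the delay is an exact whole number of samples the
#' hand samples are a bitwise-shifted copy of the face samples (the shift is
#' performed on the sample grid, not by re-evaluation), so pure-delay
#' recovery tests are exact. When `peak_delay_s` and `valley_delay_s`
#' differ, the hand signal is warped through a slowly varying delay field
#' that equals the peak delay at each systolic peak and the valley delay at
#' each diastolic valley. Independent Gaussian noise is added per site last.
#'
#' @param spec a [signal_spec()].
#' @return List with `face`, `hand` (`vbp_ppg` tibbles), `beats` (true
#'   systolic peak times, s), `valleys` (true valley times, s), and `spec`.
#' @export
generate_ppg_pair <- function(spec) {
  stopifnot(inherits(spec, "vbp_signal_spec"))
  set.seed(spec$seed)
  beats <- draw_beats(spec)
  N <- round(spec$fs * spec$duration_s)
  t <- (seq_len(N) - 1) / spec$fs

  asym <- !is.null(spec$peak_delay_s) && !is.null(spec$valley_delay_s) &&
    spec$peak_delay_s != spec$valley_delay_s
  if (!asym) {
    delay <- if (!is.null(spec$peak_delay_s)) spec$peak_delay_s else spec$transit_delay_s
    k <- delay * spec$fs
    if (abs(k - round(k)) < 1e-9) {
      k <- as.integer(round(k))
      ext <- eval_pulse((seq(-k, N - 1L)) / spec$fs, beats)
      face <- ext[(k + 1L):(k + N)]
      hand <- ext[1:N]
    } else {
      face <- eval_pulse(t, beats)
      hand <- eval_pulse(t - delay, beats)
    }
    valleys <- true_valleys(beats)
  } else {
    face <- eval_pulse(t, beats)
    valleys <- true_valleys(beats)
    knot_t <- c(beats, valleys)
    knot_d <- c(rep(spec$peak_delay_s, length(beats)),
                rep(spec$valley_delay_s, length(valleys)))
    ord <- order(knot_t)
    d_field <- approx(knot_t[ord], knot_d[ord], xout = t, rule = 2)$y
    hand <- eval_pulse(t - d_field, beats)
  }
  if (spec$noise_sd > 0) {
    face <- face + rnorm(N, 0, spec$noise_sd)
    hand <- hand + rnorm(N, 0, spec$noise_sd)
  }
  keep <- beats >= 0 & beats <= spec$duration_s
  list(face = new_ppg(face, spec$fs, "face"),
       hand = new_ppg(hand, spec$fs, "hand"),
       beats = beats[keep],
       valleys = valleys[valleys >= 0 & valleys <= spec$duration_s],
       spec = spec)
}

#' Generate a pulsatile skin-tone RGB trace
#'
#' Emulates the spatially averaged colour of living skin: a base tone whose
#' channels are multiplicatively modulated by the pulse waveform, with a
#' channel-dependent strength (green strongest, as in real skin
#' reflectance; a channel-identical modulation would be pure common-mode
#' intensity, which chrominance projection cancels by design). An optional
#' common-mode illumination drift multiplies all three channels equally.
#'
#' @param spec a [signal_spec()].
#' @param base length-3 base RGB tone on `[0, 255]`.
#' @param strength overall fractional modulation amplitude.
#' @param channel_weights per-channel relative pulsatile strengths (R, G, B).
#' @return List with `trace` (a `vbp_trace`), `signal` (the driving pulse as
#'   a `vbp_ppg`), `beats`, and `spec`.
#' @export
generate_skin_trace <- function(spec, base = c(140, 95, 75), strength = 0.03,
                                channel_weights = c(0.3, 0.8, 0.5)) {
  pair <- generate_ppg_pair(spec)
  s <- pair$face$value
  t <- pair$face$t
  drift <- 1 + spec$drift_amplitude * sin(2 * pi * spec$drift_freq_hz * t)
  trace <- structure(
    tibble(frame_index = seq_along(t) - 1L, t = t,
           r = base[1] * (1 + strength * channel_weights[1] * s) * drift,
           g = base[2] * (1 + strength * channel_weights[2] * s) * drift,
           b = base[3] * (1 + strength * channel_weights[3] * s) * drift),
    fs = spec$fs, site = "face",
    class = c("vbp_trace", class(tibble())))
  list(trace = trace, signal = pair$face, beats = pair$beats, spec = spec)
}

#' Patch layout for synthetic skin videos
#'
#' @param width,height frame size in px.
#' @param face_rect,hand_rect patch rectangles `c(x, y, w, h)` in 0-based
#'   pixel coordinates (must not overlap).
#' @param inset inner margin (px) between a patch and its ROI rectangle.
#' @return A layout list.
#' @export
video_layout <- function(width = 64, height = 48,
                         face_rect = c(8, 6, 20, 14),
                         hand_rect = c(36, 26, 20, 14), inset = 2) {
  overlap <- function(a, b) {
    !(a[1] + a[3] <= b[1] || b[1] + b[3] <= a[1] ||
        a[2] + a[4] <= b[2] || b[2] + b[4] <= a[2])
  }
  if (overlap(face_rect, hand_rect)) {
    abort("overlapping face/hand patches", class = "videobp_input_error")
  }
  stopifnot(face_rect[1] + face_rect[3] <= width,
            face_rect[2] + face_rect[4] <= height,
            hand_rect[1] + hand_rect[3] <= width,
            hand_rect[2] + hand_rect[4] <= height)
  list(width = width, height = height, face_rect = face_rect,
       hand_rect = hand_rect, inset = inset)
}

rect_corners <- function(r, inset = 0) {
  x0 <- r[1] + inset; y0 <- r[2] + inset
  x1 <- r[1] + r[3] - 1 - inset; y1 <- r[2] + r[4] - 1 - inset
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

#' Generate a pulsating-skin video with ground truth
#'
#' Renders a clip in which two non-overlapping rectangular skin patches
#' (face, hand) carry the face and hand pulse signals as multiplicative
#' modulations of a base skin tone (channel weights as in
#' [generate_skin_trace()]), on a neutral background. The returned landmark
#' fixture places eight points per site (outer patch corners and inner ROI
#' corners) and the bundled backend's ROI tables select the inner rectangle,
#' so the whole tracking-to-signal pipeline can run against known truth.
#'
#' @param spec a [signal_spec()].
#' @param layout a [video_layout()].
#' @param base_face,base_hand base skin tones (RGB on `[0, 255]`).
#' @param strength fractional modulation amplitude.
#' @param channel_weights per-channel pulsatile strengths.
#' @param background background grey level.
#' @return List with `video` ([vbp_video()]), `landmarks` (fixture tibble),
#'   `backend` ([fixture_backend()]), `rois` (true inner-ROI polygons per
#'   site), and `truth` (beats, valleys, delay, the driving `vbp_ppg`
#'   signals, layout, spec).
#' @export
generate_skin_video <- function(spec, layout = video_layout(),
                                base_face = c(140, 95, 75),
                                base_hand = c(150, 105, 85),
                                strength = 0.05,
                                channel_weights = c(0.3, 0.8, 0.5),
                                background = 100) {
  pair <- generate_ppg_pair(spec)
  N <- nrow(pair$face)
  bg <- array(background, dim = c(layout$height, layout$width, 3L))
  fr <- layout$face_rect; hr <- layout$hand_rect
  fy <- (fr[2] + 1L):(fr[2] + fr[4]); fx <- (fr[1] + 1L):(fr[1] + fr[3])
  hy <- (hr[2] + 1L):(hr[2] + hr[4]); hx <- (hr[1] + 1L):(hr[1] + hr[3])
  frames <- vector("list", N)
  for (n in seq_len(N)) {
    f <- bg
    for (c in 1:3) {
      f[fy, fx, c] <- base_face[c] *
        (1 + strength * channel_weights[c] * pair$face$value[n])
      f[hy, hx, c] <- base_hand[c] *
        (1 + strength * channel_weights[c] * pair$hand$value[n])
    }
    frames[[n]] <- f
  }
  video <- vbp_video(frames, fps = spec$fs)

  face_pts <- rbind(rect_corners(fr, 0), rect_corners(fr, layout$inset))
  hand_pts <- rbind(rect_corners(hr, 0), rect_corners(hr, layout$inset))
  landmarks <- tibble(
    frame_index = seq_len(N) - 1L,
    face = rep(list(face_pts), N),
    hand = rep(list(hand_pts), N),
    valid = TRUE)
  backend <- fixture_backend(landmarks,
                             roi_indices = list(forehead = 5:8, palm = 5:8))
  rois <- list(
    forehead = construct_roi(face_pts, "forehead", 5:8, 0L),
    palm = construct_roi(hand_pts, "palm", 5:8, 0L))
  list(video = video, landmarks = landmarks, backend = backend, rois = rois,
       truth = list(beats = pair$beats, valleys = pair$valleys,
                    delay_s = spec$transit_delay_s, face = pair$face,
                    hand = pair$hand, layout = layout, spec = spec))
}

# quantize to quarter-centimetres (binary-exact values)
qcm <- function(x) round(x * 4) / 4

#' Body proportions used by the pose-fixture generator
#'
#' Fractions of standing height, measured downward from the head top,
#' following standard anthropometric segment tables: eye line 0.064, half
#' inter-eye distance 0.0185, shoulder line 0.182 (half width 0.1295), hip
#' line 0.470 (half width 0.0955), heel base 1.0 (the ankle landmarks mark
#' the heel-floor contact so the head-to-ankle extent equals body height),
#' ankle half stance width 0.04, and heart-to-wrist distance 0.325.
#'
#' @export
pose_proportions <- list(
  eye_y = 0.064, eye_dx = 0.0185,
  shoulder_y = 0.182, shoulder_dx = 0.1295,
  hip_y = 0.470, hip_dx = 0.0955,
  ankle_y = 1.0, ankle_dx = 0.04,
  wrist_dist = 0.325
)

#' Generate a full-length pose fixture with exact distance truths
#'
#' Builds a stick-figure pose in centimetre space from standard body
#' proportions, then renders it to pixels at camera scale `p` (px/cm) plus
#' an integer pixel origin. Coordinates are quantised to 0.25 cm and the
#' heart-to-wrist offset is laid out in 5:12:13 proportion, so that for
#' integer `p` every pixel quantity is an exact floating-point multiple of
#' its centimetre truth and [vessel_length_difference()] recovers the
#' truths bit-exactly at any camera scale.
#'
#' @param height_cm subject height (quantised to 0.25 cm internally; the
#'   quantised value is returned in the truth and should be used as the
#'   demographic height downstream).
#' @param p camera scale in px/cm (integer values keep pixel arithmetic
#'   exact).
#' @param origin_px integer `c(x, y)` pixel offset of the figure's head top.
#' @param proportions a [pose_proportions]-shaped list.
#' @return List with `pose` (tibble `point`, `x`, `y` in px) and `truth`
#'   (`height_cm`, `p`, `height_px`, `distF_cm`, `distH_cm`, `L_cm`).
#' @export
generate_pose_fixture <- function(height_cm, p = 5, origin_px = c(100L, 50L),
                                  proportions = pose_proportions) {
  if (!is.finite(height_cm) || height_cm <= 0) {
    abort("height_cm must be positive", class = "videobp_input_error")
  }
  H <- qcm(height_cm)
  pr <- proportions
  eye_y <- qcm(pr$eye_y * H); eye_dx <- qcm(pr$eye_dx * H)
  sho_y <- qcm(pr$shoulder_y * H); sho_dx <- qcm(pr$shoulder_dx * H)
  hip_y <- qcm(pr$hip_y * H); hip_dx <- qcm(pr$hip_dx * H)
  ank_y <- H; ank_dx <- qcm(pr$ankle_dx * H)

  # heart anchor in cm (dyadic arithmetic: fraction 1/8 keeps it exact)
  heart_y <- sho_y + pose_anchor_table$heart_hip_fraction * (hip_y - sho_y)
  face_y <- eye_y - pose_anchor_table$face_raise_fraction * (2 * eye_dx)

  # wrist: 5:12:13 offset from the heart so the distance is exactly 13m/4 cm
  m <- max(1, round(pr$wrist_dist * H * 4 / 13))
  wrist <- c(5 * m / 4, heart_y + 12 * m / 4)

  pts_cm <- rbind(
    head_top = c(0, 0),
    left_eye = c(-eye_dx, eye_y), right_eye = c(eye_dx, eye_y),
    left_shoulder = c(-sho_dx, sho_y), right_shoulder = c(sho_dx, sho_y),
    left_hip = c(-hip_dx, hip_y), right_hip = c(hip_dx, hip_y),
    right_wrist = wrist,
    left_wrist = c(-wrist[1], wrist[2]),
    left_ankle = c(-ank_dx, ank_y), right_ankle = c(ank_dx, ank_y))

  pose <- tibble(point = rownames(pts_cm),
                 x = origin_px[1] + p * unname(pts_cm[, 1]),
                 y = origin_px[2] + p * unname(pts_cm[, 2]))

  distF_cm <- heart_y - face_y
  distH_cm <- 13 * m / 4
  list(pose = pose,
       truth = list(height_cm = H, p = p, height_px = p * H,
                    distF_cm = distF_cm, distH_cm = distH_cm,
                    L_cm = abs(distF_cm - distH_cm)))
}

# truncated-normal sampling by rejection (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# per-country demographic and blood-pressure distributions of the reference
# field cohort (mean, sd, min, max)
cohort_distributions <- list(
  India = list(age = c(45.0, 14.2, 17, 82), height = c(157, 9.6, 133, 195),
               weight = c(62.0, 11.7, 34, 101), sbp = c(118, 19.6, 85, 191),
               dbp = c(76.5, 13.1, 28, 113), p_male = 56 / 200),
  `Sierra Leone` = list(age = c(34.6, 12.9, 17, 75), height = c(159, 19.8, 68, 200),
                        weight = c(66.0, 17.5, 42, 160), sbp = c(125, 19.3, 85, 202),
                        dbp = c(80.9, 13.3, 50, 126), p_male = 59 / 200)
)

#' Generate a model-consistent synthetic cohort
#'
#' Samples demographics and true blood pressures from per-country truncated
#' normals parameterised by the reference field cohort (half the subjects
#' from each country; gender assigned by each country's observed
#' proportion; height, weight, age, SBP and DBP sampled independently
#' within each country, truncated to the observed ranges; DBP resampled
#' until pulse pressure is at least 10 mmHg). Each subject's heart-to-face
#' and heart-to-hand distances follow the [pose_proportions] fractions of
#' height with 3% lognormal individual variation (quantised to 0.25 cm),
#' and a camera scale is drawn to give pixel-space provenance. The
#' subject's transit times are then *derived from the true pressures* by
#' the closed-form model inversion with demographic-variant parameters, so
#' the cohort is exactly model-consistent: [estimate_bp()] on the stored
#' transit times reproduces the true pressures to machine precision.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param distributions per-country distribution list shaped like the
#'   default (`cohort_distributions`).
#' @param constants a [model_constants()].
#' @return A tibble with one row per subject: demographics, true pressures,
#'   geometry truths (`distF_cm`, `distH_cm`, `L_cm`, `height_px`, `p`),
#'   vessel parameters (`D`, `h`) and derived transit times (`ptt_s`,
#'   `ptt_d`).
#' @export
generate_cohort <- function(n, seed = 1L, distributions = cohort_distributions,
                            constants = model_constants()) {
  stopifnot(n >= 1)
  set.seed(seed)
  countries <- rep(names(distributions), length.out = n)
  rows <- lapply(names(distributions), function(cty) {
    idx <- which(countries == cty)
    m <- length(idx)
    if (m == 0L) return(NULL)
    d <- distributions[[cty]]
    draw <- function(par) rtnorm(m, par[1], par[2], par[3], par[4])
    age <- draw(d$age); height <- draw(d$height); weight <- draw(d$weight)
    sbp <- draw(d$sbp); dbp <- draw(d$dbp)
    for (iter in 1:100) {
      bad <- sbp - dbp < 10
      if (!any(bad)) break
      dbp[bad] <- rtnorm(sum(bad), d$dbp[1], d$dbp[2], d$dbp[3],
                         pmin(d$dbp[4], sbp[bad] - 10))
    }
    gender <- ifelse(runif(m) < d$p_male, "male", "female")
    tibble(country = cty, gender = gender, age_years = age,
           height_cm = height, weight_kg = weight,
           true_sbp_mmHg = sbp, true_dbp_mmHg = dbp)
  })
  cohort <- dplyr::bind_rows(rows)
  n_out <- nrow(cohort)
  cohort$subject_id <- sprintf("S%04d", seq_len(n_out))

  pr <- pose_proportions
  distF_frac <- (pr$shoulder_y +
                   pose_anchor_table$heart_hip_fraction * (pr$hip_y - pr$shoulder_y)) -
    (pr$eye_y - pr$eye_dx)
  cohort$distF_cm <- qcm(distF_frac * cohort$height_cm *
                           exp(rnorm(n_out, 0, 0.03)))
  cohort$distH_cm <- qcm(pr$wrist_dist * cohort$height_cm *
                           exp(rnorm(n_out, 0, 0.03)))
  cohort$L_cm <- abs(cohort$distF_cm - cohort$distH_cm)
  cohort$p <- sample(3:9, n_out, replace = TRUE)
  cohort$height_px <- cohort$p * qcm(cohort$height_cm)

  params <- build_parameters("demographic", demo = cohort,
                             geometry = cohort$L_cm, constants = constants)
  cohort$D <- params$D_d
  cohort$h <- params$h
  cohort$ptt_s <- invert_ptt(cohort$true_sbp_mmHg, params, "systolic")
  cohort$ptt_d <- invert_ptt(cohort$true_dbp_mmHg, params, "diastolic")
  dplyr::relocate(cohort, "subject_id")
}
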