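#' Pipeline configuration
#'
#' One serialisable object holding every tunable of the end-to-end
#' estimator. Defaults equal the documented model values wherever one
#' exists (band-pass 0.25-15 Hz; fixed-variant vessel constants via
#' [build_parameters()]); the remaining defaults are the package's design
#' choices (filter order 4, CHROM window 1.6 s, 0.4 s peak refractory
#' interval, 1 s filter-transient trim, 2 s tracking-gap limit).
#'
#' @param variant `"demographic"` or `"fixed"`.
#' @param low_hz,high_hz band-pass cutoffs (Hz).
#' @param filter_order total Butterworth band-pass order (even).
#' @param chrom_window_s,chrom_overlap CHROM sliding-window parameters.
#' @param min_peak_distance_s,peak_height_frac peak-detector settings.
#' @param min_pairs fewest event pairs for a reportable transit time.
#' @param max_lag pairing window (s); `NULL` for the half-median-beat rule.
#' @param trim_s seconds trimmed from each signal end before event
#'   detection (filter edge transients).
#' @param max_gap_s longest tolerated run of untrackable frames (s).
#' @param min_fps,min_width,min_height,strict_video capture requirements and
#'   their enforcement.
#' @param ds_ratio systolic/diastolic diameter ratio.
#' @param constants a [model_constants()].
#' @param seed optional integer recorded for provenance.
#' @return A `vbp_config` list.
#' @export
vbp_config <- function(variant = c("demographic", "fixed"),
                       low_hz = 0.25, high_hz = 15, filter_order = 4,
                       chrom_window_s = 1.6, chrom_overlap = 0.5,
                       min_peak_distance_s = 0.4, peak_height_frac = 0.3,
                       min_pairs = 5L, max_lag = NULL, trim_s = 1,
                       max_gap_s = 2, min_fps = 30, min_width = 320,
                       min_height = 240, strict_video = FALSE,
                       ds_ratio = 1, constants = model_constants(),
                       seed = NULL) {
  variant <- match.arg(variant)
  structure(list(variant = variant, low_hz = low_hz, high_hz = high_hz,
                 filter_order = filter_order, chrom_window_s = chrom_window_s,
                 chrom_overlap = chrom_overlap,
                 min_peak_distance_s = min_peak_distance_s,
                 peak_height_frac = peak_height_frac, min_pairs = min_pairs,
                 max_lag = max_lag, trim_s = trim_s, max_gap_s = max_gap_s,
                 min_fps = min_fps, min_width = min_width,
                 min_height = min_height, strict_video = strict_video,
                 ds_ratio = ds_ratio, constants = constants, seed = seed),
            class = "vbp_config")
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$constants <- unclass(snap$constants)
  snap
}

trim_ppg <- function(ppg, trim_s) {
  if (trim_s <= 0) return(ppg)
  fs <- attr(ppg, "fs")
  k <- round(trim_s * fs)
  n <- nrow(ppg)
  if (n - 2 * k < 4 * fs) {
    abort("signal too short after transient trimming; record a longer video",
          class = "videobp_quality_error")
  }
  new_ppg(ppg$value[(k + 1):(n - k)], fs, attr(ppg, "site"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "videobp_stage_error")) stop(e)
    abort(sprintf("[%s] %s", name, conditionMessage(e)),
          class = c("videobp_stage_error", class(e)[1]))
  })
}

#' End-to-end blood-pressure estimation from a video
#'
#' Runs the full pipeline on one subject: landmark tracking and frame
#' quality control, forehead/palm ROI construction, spatial RGB averaging,
#' chrominance pulse extraction, zero-phase band-pass filtering, transit
#' time measurement, anthropometric geometry, vessel-parameter assembly and
#' the pressure-model inversion — one SBP/DBP pair per video. Errors
#' surface with the failing stage's name; all intermediates are attached to
#' the result for provenance.
#'
#' @param video a [vbp_video()] (or a path readable by
#'   [read_video_frames()]).
#' @param backend a [landmark_backend()] providing per-frame face/hand
#'   landmarks.
#' @param pose full-length-image pose landmarks (tibble `point`, `x`, `y`,
#'   or a path readable by [read_pose_json()]); required for the
#'   demographic variant.
#' @param demographics one-row data frame with `height_cm`, `weight_kg`,
#'   `age_years`; required for the demographic variant.
#' @param config a [vbp_config()].
#' @return A `vbp_bp` tibble (one row) with attributes `geometry`,
#'   `transit`, `counts` (frames kept/dropped, event pairs), `qc` and
#'   `config`.
#' @export
estimate_bp_video <- function(video, backend, pose = NULL,
                              demographics = NULL, config = vbp_config()) {
  if (is.character(video)) video <- read_video_frames(video)
  if (is.character(pose)) pose <- read_pose_json(pose)
  stage("video", validate_video(video, config$min_fps, config$min_width,
                                config$min_height, strict = config$strict_video))

  lms <- stage("tracking", track_landmarks(video, backend))
  qc_frames <- stage("tracking", drop_invalid_frames(lms, video$fps,
                                                     config$max_gap_s))
  kept <- qc_frames$kept

  roi_of <- function(points_col, site, idx) {
    purrr::map2(kept[[points_col]], kept$frame_index,
                ~ construct_roi(.x, site, idx, .y))
  }
  rois_face <- stage("roi", roi_of("face", "forehead",
                                   backend$roi_indices$forehead))
  rois_hand <- stage("roi", roi_of("hand", "palm", backend$roi_indices$palm))

  one_signal <- function(rois, site) {
    tr <- mean_rgb_trace(video, rois, kept$frame_index, site = site)
    tr <- regularize_trace(tr, frame_count = video$frame_count)
    ppg <- chrom_extract(tr, window_s = config$chrom_window_s,
                         overlap = config$chrom_overlap)
    ppg <- bandpass(ppg, config$low_hz, config$high_hz, config$filter_order)
    trim_ppg(ppg, config$trim_s)
  }
  face <- stage("rppg", one_signal(rois_face, "face"))
  hand <- stage("rppg", one_signal(rois_hand, "hand"))

  tt <- stage("transit", compute_transit_times(
    face, hand, max_lag = config$max_lag, min_pairs = config$min_pairs,
    min_distance_s = config$min_peak_distance_s,
    height_frac = config$peak_height_frac))

  if (config$variant == "demographic") {
    if (is.null(pose) || is.null(demographics)) {
      abort("[parameters] demographic variant requires pose landmarks and demographics",
            class = c("videobp_stage_error", "videobp_input_error"))
    }
    demographics <- stage("parameters", validate_demographics(demographics))
    pd <- stage("geometry", pose_distances(pose))
    geom <- stage("geometry", vessel_length_difference(
      pd$height_px, pd$distF_px, pd$distH_px, demographics$height_cm[1]))
    params <- stage("parameters", build_parameters(
      "demographic", demo = demographics, geometry = geom,
      constants = config$constants, ds_ratio = config$ds_ratio))
  } else {
    geom <- NULL
    params <- build_parameters("fixed", constants = config$constants,
                               ds_ratio = config$ds_ratio)
  }

  bp <- stage("pressure", estimate_bp(tt, params))
  structure(bp,
            geometry = geom, transit = tt,
            counts = list(frames_total = video$frame_count,
                          frames_kept = nrow(kept),
                          frames_dropped = length(qc_frames$dropped_indices),
                          pairs_systolic = tt$n_pairs_s,
                          pairs_diastolic = tt$n_pairs_d),
            qc = c(attr(bp, "qc"), tt$qc),
            config = config_snapshot(config),
            class = class(bp))
}

#' Batch estimation over a manifest
#'
#' Processes independent per-subject rows; a failure in one subject is
#' recorded as a structured failure record and the batch continues.
#'
#' @param manifest data frame (or CSV path) with columns `subject_id`,
#'   `video` (frame-directory path), `landmarks` (JSON-lines path), and for
#'   the demographic variant `pose` (JSON path), `height_cm`, `weight_kg`,
#'   `age_years`.
#' @param config a [vbp_config()].
#' @param out_jsonl optional path: one JSON result/failure record per line.
#' @return Tibble with one row per manifest row: `subject_id`, `ok`,
#'   estimates (NA on failure) and `error`.
#' @export
run_batch <- function(manifest, config = vbp_config(), out_jsonl = NULL) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  if (nrow(manifest) == 0L) {
    warn("empty manifest: no subjects to process")
    out <- tibble(subject_id = character(0), ok = logical(0),
                  sbp_mmHg = numeric(0), dbp_mmHg = numeric(0),
                  ptt_s = numeric(0), ptt_d = numeric(0),
                  error = character(0))
    if (!is.null(out_jsonl)) writeLines(character(0), out_jsonl)
    return(out)
  }
  con <- if (!is.null(out_jsonl)) file(out_jsonl, "w")
  if (!is.null(con)) on.exit(close(con))

  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, , drop = FALSE]
    sid <- as.character(row$subject_id %||% i)
    res <- tryCatch({
      demo <- if (all(c("height_cm", "weight_kg", "age_years") %in% names(row)) &&
                  !is.na(row$height_cm)) {
        row[, intersect(c("subject_id", "height_cm", "weight_kg", "age_years",
                          "gender", "country"), names(row)), drop = FALSE]
      }
      pose <- if ("pose" %in% names(row) && !is.na(row$pose)) row$pose
      bp <- estimate_bp_video(row$video, jsonl_backend(row$landmarks),
                              pose = pose, demographics = demo,
                              config = config)
      if (!is.null(con)) writeLines(write_bp_json(bp, subject_id = sid), con)
      tibble(subject_id = sid, ok = TRUE, sbp_mmHg = bp$sbp_mmHg,
             dbp_mmHg = bp$dbp_mmHg, ptt_s = bp$ptt_s, ptt_d = bp$ptt_d,
             error = NA_character_)
    }, error = function(e) {
      if (!is.null(con)) {
        writeLines(jsonlite::toJSON(list(subject_id = sid, ok = FALSE,
                                         error = conditionMessage(e)),
                                    auto_unbox = TRUE), con)
      }
      tibble(subject_id = sid, ok = FALSE, sbp_mmHg = NA_real_,
             dbp_mmHg = NA_real_, ptt_s = NA_real_, ptt_d = NA_real_,
             error = conditionMessage(e))
    })
    res
  })
  dplyr::bind_rows(rows)
}
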