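#' Landmark provider backends
#'
#' Face/hand landmark tracking is pluggable: any detector that can map a
#' frame to a set of face points and hand points can drive the pipeline.
#' A backend declares how many points it emits per site and which point
#' indices bound the forehead and palm regions of interest, then supplies a
#' `detect(frame, frame_index)` function returning
#' `list(face = <n_face x 2 matrix>, hand = <n_hand x 2 matrix>, valid = TRUE/FALSE)`
#' in 0-based pixel coordinates.
#'
#' Two providers are bundled:
#' * [fixture_backend()] replays a precomputed landmark table (deterministic,
#'   used by the synthetic generators and tests);
#' * [jsonl_backend()] ingests per-frame landmarks produced by an external
#'   detector (e.g. a mediapipe run) from the JSON-lines interchange format
#'   `{"frame": i, "face": [[x,y],...], "hand": [[x,y],...], "valid": true}`.
#'
#' @param name backend label.
#' @param n_face,n_hand declared point counts per site.
#' @param roi_indices named list with integer vectors `forehead` and `palm`:
#'   1-based indices into the face (resp. hand) point set, in polygon vertex
#'   order.
#' @param detect function `(frame, frame_index) -> list(face, hand, valid)`.
#' @return A `vbp_backend` object.
#' @export
landmark_backend <- function(name, n_face, n_hand, roi_indices, detect) {
  stopifnot(is.function(detect),
            is.list(roi_indices),
            all(c("forehead", "palm") %in% names(roi_indices)))
  structure(list(name = name, n_face = as.integer(n_face),
                 n_hand = as.integer(n_hand),
                 roi_indices = roi_indices, detect = detect),
            class = "vbp_backend")
}

#' @rdname landmark_backend
#' @param landmarks a landmark tibble as returned by [track_landmarks()] or
#'   [read_landmarks_jsonl()]: columns `frame_index` (0-based), `face`
#'   (list of matrices), `hand` (list of matrices), `valid`.
#' @export
fixture_backend <- function(landmarks, roi_indices = NULL) {
  stopifnot(is.data.frame(landmarks),
            all(c("frame_index", "face", "hand", "valid") %in% names(landmarks)))
  first_valid <- which(landmarks$valid)[1L]
  if (is.na(first_valid)) abort("fixture has no valid frames", class = "videobp_input_error")
  n_face <- nrow(landmarks$face[[first_valid]])
  n_hand <- nrow(landmarks$hand[[first_valid]])
  if (is.null(roi_indices)) {
    roi_indices <- list(forehead = seq_len(min(4L, n_face)),
                        palm = seq_len(min(4L, n_hand)))
  }
  landmark_backend(
    name = "fixture", n_face = n_face, n_hand = n_hand,
    roi_indices = roi_indices,
    detect = function(frame, frame_index) {
      row <- which(landmarks$frame_index == frame_index)
      if (length(row) != 1L) {
        return(list(face = NULL, hand = NULL, valid = FALSE))
      }
      list(face = landmarks$face[[row]], hand = landmarks$hand[[row]],
           valid = isTRUE(landmarks$valid[row]))
    }
  )
}

#' @rdname landmark_backend
#' @param path JSON-lines file of per-frame landmarks.
#' @export
jsonl_backend <- function(path, roi_indices = NULL) {
  fixture_backend(read_landmarks_jsonl(path), roi_indices = roi_indices)
}

#' Read / write per-frame landmarks as JSON lines
#'
#' One JSON object per line:
#' `{"frame": i, "face": [[x,y],...], "hand": [[x,y],...], "valid": true}`,
#' with 0-based frame indices and 0-based pixel coordinates.
#'
#' @param path file path.
#' @return `read_landmarks_jsonl()` returns a tibble with columns
#'   `frame_index`, `face`, `hand`, `valid`.
#' @export
read_landmarks_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  as_mat <- function(x) {
    if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), ncol = 2))
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    storage.mode(m) <- "double"
    m
  }
  tibble(
    frame_index = vapply(recs, function(r) as.integer(r$frame), integer(1)),
    face = lapply(recs, function(r) as_mat(r$face)),
    hand = lapply(recs, function(r) as_mat(r$hand)),
    valid = vapply(recs, function(r) isTRUE(r$valid), logical(1))
  )
}

#' @rdname read_landmarks_jsonl
#' @param landmarks a landmark tibble.
#' @export
write_landmarks_jsonl <- function(landmarks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(landmarks))) {
    rec <- list(frame = landmarks$frame_index[i],
                face = landmarks$face[[i]],
                hand = landmarks$hand[[i]],
                valid = landmarks$valid[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Track face and hand landmarks across a video
#'
#' Runs the backend's detector on every frame and collects one landmark set
#' per frame. Frames where either site fails to detect are kept in the table
#' with `valid = FALSE` so that downstream quality control can decide what to
#' drop; a backend returning a malformed point set (wrong count, out of
#' bounds, non-finite) is a hard error naming the frame.
#'
#' @param video a [vbp_video()].
#' @param backend a [landmark_backend()].
#' @return Tibble with columns `frame_index` (0-based), `t` (seconds),
#'   `face`, `hand` (list columns of `n x 2` matrices), `valid`.
#' @export
track_landmarks <- function(video, backend) {
  stopifnot(inherits(video, "vbp_video"), inherits(backend, "vbp_backend"))
  n <- video$frame_count
  face <- vector("list", n); hand <- vector("list", n); valid <- logical(n)
  for (i in seq_len(n)) {
    det <- backend$detect(video$frames[[i]], i - 1L)
    ok <- isTRUE(det$valid)
    if (ok) {
      check_points(det$face, backend$n_face, video, i - 1L, "face")
      check_points(det$hand, backend$n_hand, video, i - 1L, "hand")
    }
    face[[i]] <- det$face %||% matrix(numeric(0), ncol = 2)
    hand[[i]] <- det$hand %||% matrix(numeric(0), ncol = 2)
    valid[i] <- ok
  }
  tibble(frame_index = seq_len(n) - 1L, t = (seq_len(n) - 1L) / video$fps,
         face = face, hand = hand, valid = valid)
}

check_points <- function(pts, n_expected, video, frame_index, site) {
  if (!is.matrix(pts) || ncol(pts) != 2L || nrow(pts) != n_expected ||
      !all(is.finite(pts))) {
    abort(sprintf("backend returned malformed %s points at frame %d",
                  site, frame_index), class = "videobp_backend_error")
  }
  if (any(pts[, 1] < 0 | pts[, 1] > video$width - 1 |
          pts[, 2] < 0 | pts[, 2] > video$height - 1)) {
    abort(sprintf("backend returned out-of-bounds %s points at frame %d",
                  site, frame_index), class = "videobp_backend_error")
  }
  invisible(pts)
}

#' Drop untrackable frames
#'
#' Partitions frames into kept (valid) and dropped (invalid) sets, preserving
#' order, and errors when tracking is unusable: no valid frame at all, or a
#' consecutive run of invalid frames longer than `max_gap_s` seconds (such a
#' gap would silently tear the pulse trace apart; shorter gaps are bridged by
#' interpolation downstream).
#'
#' @param landmarks tibble from [track_landmarks()].
#' @param fps frames per second, used to convert the gap limit to frames.
#' @param max_gap_s longest tolerated run of invalid frames, seconds.
#' @return List with `kept` (tibble of valid rows), `kept_indices` and
#'   `dropped_indices` (0-based frame indices).
#' @export
drop_invalid_frames <- function(landmarks, fps, max_gap_s = 2) {
  stopifnot(is.data.frame(landmarks), "valid" %in% names(landmarks))
  if (!any(landmarks$valid)) {
    abort("no trackable frames", class = "videobp_quality_error")
  }
  if (!all(landmarks$valid)) {
    runs <- rle(!landmarks$valid)
    worst <- max(runs$lengths[runs$values])
    if (worst > max_gap_s * fps) {
      abort(sprintf(
        "untrackable gap of %.2f s exceeds the %.2f s limit; recapture the video",
        worst / fps, max_gap_s), class = "videobp_quality_error")
    }
  }
  list(kept = landmarks[landmarks$valid, , drop = FALSE],
       kept_indices = landmarks$frame_index[landmarks$valid],
       dropped_indices = landmarks$frame_index[!landmarks$valid])
}

#' Construct a region-of-interest polygon from one frame's landmarks
#'
#' The ROI is the polygon through a fixed, documented subset of landmark
#' points: the backend's `roi_indices$forehead` rows of the face point set
#' (spanning the upper face above the eyebrows) or `roi_indices$palm` rows of
#' the hand point set (covering the palm centre). Because the vertices are
#' landmark points themselves, the polygon translates and scales with the
#' subject's apparent size automatically.
#'
#' @param points `n x 2` matrix of landmark coordinates for the site's point
#'   set (face points for `site = "forehead"`, hand points for
#'   `site = "palm"`).
#' @param site `"forehead"` or `"palm"`.
#' @param indices 1-based vertex indices into `points`, in order; defaults to
#'   the backend table when called through the pipeline.
#' @param frame_index 0-based frame index recorded on the polygon.
#' @return A `vbp_roi` object: list with `site`, `vertices` (matrix),
#'   `frame_index`.
#' @export
construct_roi <- function(points, site = c("forehead", "palm"), indices,
                          frame_index = 0L) {
  site <- match.arg(site)
  stopifnot(is.matrix(points), ncol(points) == 2L)
  if (length(indices) < 3L) {
    abort("an ROI polygon needs at least 3 vertices", class = "videobp_input_error")
  }
  if (max(indices) > nrow(points) || min(indices) < 1L) {
    abort("ROI indices outside the landmark point set", class = "videobp_input_error")
  }
  verts <- points[indices, , drop = FALSE]
  if (!polygon_is_simple(verts)) {
    abort(sprintf("self-intersecting %s polygon at frame %d", site, frame_index),
          class = "videobp_quality_error")
  }
  if (abs(polygon_area(verts)) < .Machine$double.eps * 100) {
    abort(sprintf("degenerate %s polygon (zero area) at frame %d",
                  site, frame_index), class = "videobp_quality_error")
  }
  structure(list(site = site, vertices = verts,
                 frame_index = as.integer(frame_index)),
            class = "vbp_roi")
}

# Shoelace signed area.
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Simplicity test: no two non-adjacent edges intersect. O(n^2), n is tiny.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_cross(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a, b) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b[1, ], b[2, ], a[1, ]); d2 <- d(b[1, ], b[2, ], a[2, ])
  d3 <- d(a[1, ], a[2, ], b[1, ]); d4 <- d(a[1, ], a[2, ], b[2, ])
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}
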