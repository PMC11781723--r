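#' Anchor-point conventions for full-length pose measurements
#'
#' The heart-to-face and heart-to-hand distances are read off a full-length
#' standing image through three anchor points, each a fixed function of
#' named pose landmarks:
#'
#' * **heart anchor** - midpoint of the two shoulder landmarks, displaced
#'   one-eighth of the shoulder-midpoint-to-hip-midpoint distance toward the
#'   hips (a dyadic fraction, so the anchor arithmetic is exact in binary
#'   floating point and the camera-scale invariance of derived lengths is
#'   bit-exact);
#' * **face anchor** - midpoint of the two eye landmarks, raised by half the
#'   eye-to-eye distance (a forehead-centre proxy);
#' * **hand anchor** - the wrist landmark (right wrist by default).
#'
#' Distances are straight-line pixel Euclidean distances; arterial
#' tortuosity is absorbed into the proportionality constant of the
#' pixel-to-cm scaling. The subject's pixel height is the vertical extent
#' from the head-top landmark to the mean ankle landmark.
#'
#' @format A named list of the required pose landmark names.
#' @export
pose_anchor_table <- list(
  height = c("head_top", "left_ankle", "right_ankle"),
  heart = c("left_shoulder", "right_shoulder", "left_hip", "right_hip"),
  face = c("left_eye", "right_eye"),
  hand = "right_wrist",
  heart_hip_fraction = 0.125,
  face_raise_fraction = 0.5
)

#' Pixel distances from a full-length standing pose
#'
#' Computes the subject's pixel height and the heart-to-face / heart-to-hand
#' pixel distances from named pose landmarks (see [pose_anchor_table] for
#' the anchor conventions). The pose may come from any landmark provider;
#' [read_pose_json()] ingests an external detector's output and
#' [generate_pose_fixture()] builds synthetic poses with known truth.
#'
#' @param pose a data frame with columns `point`, `x`, `y` (0-based pixel
#'   coordinates, y downward) containing at least the landmarks named in
#'   [pose_anchor_table].
#' @return List with `height_px`, `distF_px`, `distH_px`.
#' @export
pose_distances <- function(pose) {
  stopifnot(is.data.frame(pose), all(c("point", "x", "y") %in% names(pose)))
  need <- c("head_top", "left_ankle", "right_ankle", "left_shoulder",
            "right_shoulder", "left_hip", "right_hip", "left_eye",
            "right_eye", "right_wrist")
  missing <- setdiff(need, pose$point)
  if (length(missing)) {
    abort(paste0("pose detection failure: missing landmarks ",
                 paste(missing, collapse = ", ")),
          class = "videobp_input_error")
  }
  pt <- function(name) {
    row <- pose[pose$point == name, , drop = FALSE][1L, ]
    unname(c(row$x, row$y))
  }
  mid <- function(a, b) (pt(a) + pt(b)) / 2

  ankle_y <- (pt("left_ankle")[2] + pt("right_ankle")[2]) / 2
  height_px <- abs(ankle_y - pt("head_top")[2])

  shoulder_mid <- mid("left_shoulder", "right_shoulder")
  hip_mid <- mid("left_hip", "right_hip")
  heart <- shoulder_mid + pose_anchor_table$heart_hip_fraction * (hip_mid - shoulder_mid)

  eye_mid <- mid("left_eye", "right_eye")
  eye_dist <- sqrt(sum((pt("left_eye") - pt("right_eye"))^2))
  face <- eye_mid - c(0, pose_anchor_table$face_raise_fraction * eye_dist)

  hand <- pt("right_wrist")

  euclid <- function(a, b) sqrt(sum((a - b)^2))
  list(height_px = height_px,
       distF_px = euclid(heart, face),
       distH_px = euclid(heart, hand))
}

#' Read a pose landmark file (JSON)
#'
#' Expects `{"points": {"head_top": [x, y], ...}}` or a flat
#' `{"head_top": [x, y], ...}` object.
#'
#' @param path JSON file.
#' @return Tibble with columns `point`, `x`, `y`.
#' @export
read_pose_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$points)) obj <- obj$points
  tibble(point = names(obj),
         x = vapply(obj, function(p) as.numeric(p[[1]]), numeric(1)),
         y = vapply(obj, function(p) as.numeric(p[[2]]), numeric(1)))
}

#' @rdname read_pose_json
#' @param pose a pose tibble.
#' @export
write_pose_json <- function(pose, path) {
  pts <- setNames(lapply(seq_len(nrow(pose)), function(i) c(pose$x[i], pose$y[i])),
                  pose$point)
  jsonlite::write_json(list(points = pts), path, digits = NA)
  invisible(path)
}

#' Pixel-per-centimetre scale constant
#'
#' The subject's measured height ties the pixel scale of the full-length
#' image to the real world: `p = height_px / height_cm`. Because `p`
#' absorbs the camera distance, all pixel-to-cm conversions that use it are
#' independent of how far the subject stood from the camera.
#'
#' @param height_px subject height in the image, pixels (> 0).
#' @param height_cm measured height, cm (> 0).
#' @return Scale constant `p` in px/cm.
#' @examples
#' estimate_scale(800, 160) # 5 px/cm
#' @export
estimate_scale <- function(height_px, height_cm) {
  if (!is.finite(height_px) || height_px <= 0 ||
      !is.finite(height_cm) || height_cm <= 0) {
    abort("height_px and height_cm must be positive", class = "videobp_input_error")
  }
  height_px / height_cm
}

#' Blood-vessel length difference from pose pixel distances
#'
#' Converts the heart-to-face and heart-to-hand pixel distances to cm with
#' the scale constant `p = height_px / height_cm` and takes the vessel
#' length difference as the magnitude `L = |distF_cm - distH_cm|`. `L` is
#' exactly invariant under uniform scaling of all pixel quantities (camera
#' distance drops out of the ratios).
#'
#' @param height_px,distF_px,distH_px pixel measurements from
#'   [pose_distances()].
#' @param height_cm measured subject height in cm.
#' @return A `vbp_geometry` one-row tibble: `height_px`, `p`, `distF_cm`,
#'   `distH_cm`, `L_cm`, plus a `qc` attribute.
#' @examples
#' vessel_length_difference(800, 350, 250, 160) # p = 5, L = 20 cm
#' @export
vessel_length_difference <- function(height_px, distF_px, distH_px, height_cm) {
  if (any(!is.finite(c(height_px, distF_px, distH_px, height_cm))) ||
      any(c(height_px, distF_px, distH_px, height_cm) <= 0)) {
    abort("all pose/height inputs must be positive", class = "videobp_input_error")
  }
  p <- estimate_scale(height_px, height_cm)
  distF_cm <- distF_px / p
  distH_cm <- distH_px / p
  L_cm <- abs(distF_cm - distH_cm)
  qc <- character(0)
  if (L_cm == 0) {
    warn("L = 0: blood pressure is undefined at zero path-length difference")
    qc <- c(qc, "zero vessel length difference")
  }
  if (L_cm >= height_cm) {
    abort(sprintf("implausible geometry: L = %.1f cm >= height %.1f cm",
                  L_cm, height_cm), class = "videobp_quality_error")
  }
  structure(
    tibble(height_px = height_px, p = p, distF_cm = distF_cm,
           distH_cm = distH_cm, L_cm = L_cm),
    qc = qc,
    class = c("vbp_geometry", class(tibble())))
}

#' Validate a demographics record
#'
#' Checks presence and positivity of `height_cm`, `weight_kg`, `age_years`
#' and warns (without failing) when values fall outside the plausibility
#' envelope seen in large field cohorts: height 68-210 cm, weight 30-170 kg,
#' age 15-90 years.
#'
#' @param demo data frame with columns `height_cm`, `weight_kg`, `age_years`
#'   (and optionally `subject_id`, `gender`, `country`).
#' @return `demo` as a tibble, invisibly validated.
#' @export
validate_demographics <- function(demo) {
  stopifnot(is.data.frame(demo))
  need <- c("height_cm", "weight_kg", "age_years")
  missing <- setdiff(need, names(demo))
  if (length(missing)) {
    abort(paste0("demographics missing column(s): ", paste(missing, collapse = ", ")),
          class = "videobp_input_error")
  }
  for (col in need) {
    v <- demo[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("demographics column %s must be positive and finite", col),
            class = "videobp_input_error")
    }
  }
  soft <- list(height_cm = c(68, 210), weight_kg = c(30, 170), age_years = c(15, 90))
  for (col in names(soft)) {
    out <- demo[[col]] < soft[[col]][1] | demo[[col]] > soft[[col]][2]
    if (any(out)) {
      warn(sprintf("%d %s value(s) outside the plausible range [%g, %g]",
                   sum(out), col, soft[[col]][1], soft[[col]][2]))
    }
  }
  as_tibble(demo)
}
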