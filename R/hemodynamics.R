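#' Model constants for the pressure-elasticity law
#'
#' Blood density `rho` (kg/m^3), zero-pressure elastic modulus `E0` and the
#' exponential pressure-elasticity coefficient `alpha` (per mmHg) of
#' `E = E0 * exp(alpha * BP)`. These show no meaningful demographic
#' variability and are treated as constants; the defaults are the standard
#' literature values used throughout the package.
#'
#' The constants, the diameter and the wall thickness enter blood pressure
#' only through the products `rho * L^2 * D / (h * E0)`, so the diameter and
#' thickness units cancel in the `D/h` ratio; only `L` must be in metres.
#' A different unit table can be supplied explicitly.
#'
#' @param rho blood density (default 1060 kg/m^3).
#' @param E0 zero-pressure elastic modulus (default 1005, model units).
#' @param alpha elasticity-pressure coefficient (default 0.017 per mmHg).
#' @return A `vbp_constants` list.
#' @export
model_constants <- function(rho = 1060, E0 = 1005, alpha = 0.017) {
  stopifnot(rho > 0, E0 > 0, alpha > 0)
  structure(list(rho = rho, E0 = E0, alpha = alpha), class = "vbp_constants")
}

#' Arterial diameter from demographics
#'
#' Empirical regression of arterial diameter on height, age and body-mass
#' index (weight over height in metres squared):
#' `D = -0.258 + 0.029 * height_cm + 0.006 * age_years + 0.036 * BMI`.
#' The diameter is assumed constant along the vessel. Output is in the
#' regression's native (millimetre-scale) units; only the ratio `D/h`
#' enters the pressure model, so the unit cancels against
#' [wall_thickness()].
#'
#' @param demo data frame with columns `height_cm`, `age_years`,
#'   `weight_kg` (vectorised over rows).
#' @return Numeric vector of diameters.
#' @examples
#' artery_diameter(data.frame(height_cm = 158.1, age_years = 40.35,
#'                            weight_kg = 63.80))
#' @export
artery_diameter <- function(demo) {
  demo <- validate_demographics(demo)
  bmi <- demo$weight_kg / (demo$height_cm / 100)^2
  d <- -0.258 + 0.029 * demo$height_cm + 0.006 * demo$age_years + 0.036 * bmi
  if (any(d <= 0)) {
    abort("arterial diameter formula out of validity range (non-positive result)",
          class = "videobp_input_error")
  }
  d
}

#' Arterial wall thickness from demographics
#'
#' Empirical regression `h = 0.25 + 0.005 * age_years + 0.005 * BMI`
#' (BMI = weight over squared height in metres). Same unit convention as
#' [artery_diameter()].
#'
#' @inheritParams artery_diameter
#' @return Numeric vector of wall thicknesses.
#' @export
wall_thickness <- function(demo) {
  demo <- validate_demographics(demo)
  bmi <- demo$weight_kg / (demo$height_cm / 100)^2
  0.25 + 0.005 * demo$age_years + 0.005 * bmi
}

#' Assemble vessel parameters for a blood-pressure model variant
#'
#' The *demographic* variant derives per-subject parameters: `L` from the
#' full-length-image geometry (cm converted to metres here, once), and
#' diameter/thickness from the demographic regressions. The *fixed* variant
#' uses literature constants for every subject: `L = 0.2` m, radius 0.005 m
#' (diameter 0.01 m) and `h = 0.001` m.
#'
#' A single diameter serves both branches by default; a systolic/diastolic
#' diameter ratio is exposed as `ds_ratio` (`D_s = ds_ratio * D_d`,
#' default 1).
#'
#' @param variant `"demographic"` or `"fixed"`.
#' @param demo demographics data frame (required for the demographic
#'   variant; vectorised over rows).
#' @param geometry a `vbp_geometry` (or data frame with `L_cm`, one row per
#'   subject, or a numeric vector of `L_cm`); required for the demographic
#'   variant.
#' @param constants a [model_constants()] list.
#' @param ds_ratio systolic-to-diastolic diameter ratio (default 1).
#' @param n number of (identical) parameter rows for the fixed variant.
#' @return A `vbp_params` tibble with columns `variant`, `L_m`, `D_s`,
#'   `D_d`, `h` and a `constants` attribute.
#' @export
build_parameters <- function(variant = c("demographic", "fixed"), demo = NULL,
                             geometry = NULL, constants = model_constants(),
                             ds_ratio = 1, n = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(constants, "vbp_constants"), ds_ratio > 0)
  if (variant == "fixed") {
    n <- n %||% 1L
    out <- tibble(variant = "fixed", L_m = rep(0.2, n), D_s = 0.01 * ds_ratio,
                  D_d = 0.01, h = 0.001)
  } else {
    if (is.null(demo) || is.null(geometry)) {
      abort("the demographic variant requires both demographics and geometry",
            class = "videobp_input_error")
    }
    L_cm <- if (is.numeric(geometry)) geometry else geometry$L_cm
    if (any(L_cm <= 0)) {
      abort("model undefined at L <= 0", class = "videobp_input_error")
    }
    D <- artery_diameter(demo)
    h <- wall_thickness(demo)
    if (length(L_cm) == 1L && length(D) > 1L) L_cm <- rep(L_cm, length(D))
    stopifnot(length(L_cm) == length(D))
    out <- tibble(variant = "demographic", L_m = L_cm / 100,
                  D_s = D * ds_ratio, D_d = D, h = h)
  }
  structure(out, constants = constants,
            class = c("vbp_params", class(tibble())))
}

# (1/alpha) * ln(rho * L^2 * D / (h * E0)) - (2/alpha) * ln(PTT)
mk_bp <- function(ptt, L, D, h, k) {
  (1 / k$alpha) * log(k$rho * L^2 * D / (h * k$E0)) - (2 / k$alpha) * log(ptt)
}

#' Blood pressure from pulse transit times (modified Moens-Korteweg)
#'
#' Inverts the pulse-wave-velocity model. Combining the Moens-Korteweg
#' relation `PWV^2 = E h / (rho D)` with the exponential elasticity law
#' `E = E0 exp(alpha BP)` and `PWV = L / PTT` gives
#' `BP = -(2/alpha) ln(PTT) + (1/alpha) ln(rho L^2 D / (h E0))`,
#' evaluated separately on the systolic branch (peak-peak transit time,
#' systolic diameter) and the diastolic branch (valley-valley transit time,
#' diastolic diameter). Pulse wave velocities `L/PTT` are recorded
#' alongside, and estimates outside 20-300 mmHg or with SBP <= DBP are
#' flagged in `qc`, never clipped.
#'
#' @param ptt a `vbp_transit` from [compute_transit_times()], or a list/data
#'   frame with elements `ptt_s`, `ptt_d` (seconds; vectorised).
#' @param params a `vbp_params` from [build_parameters()] (rows recycled to
#'   the PTT length if a single row).
#' @return A `vbp_bp` tibble: `sbp_mmHg`, `dbp_mmHg`, `ptt_s`, `ptt_d`,
#'   `pwv_s`, `pwv_d`, `variant`, `L_m`, `D_s`, `D_d`, `h`, plus `constants`
#'   and `qc` attributes.
#' @export
estimate_bp <- function(ptt, params) {
  stopifnot(inherits(params, "vbp_params"))
  k <- attr(params, "constants")
  ptt_s <- ptt$ptt_s; ptt_d <- ptt$ptt_d
  if (any(!is.finite(c(ptt_s, ptt_d))) || any(c(ptt_s, ptt_d) <= 0)) {
    abort("model undefined at PTT <= 0", class = "videobp_input_error")
  }
  n <- max(length(ptt_s), nrow(params))
  if (nrow(params) == 1L && n > 1L) params <- params[rep(1L, n), ]
  if (length(ptt_s) == 1L && n > 1L) { ptt_s <- rep(ptt_s, n); ptt_d <- rep(ptt_d, n) }
  if (any(params$L_m <= 0)) abort("model undefined at L <= 0",
                                  class = "videobp_input_error")
  sbp <- mk_bp(ptt_s, params$L_m, params$D_s, params$h, k)
  dbp <- mk_bp(ptt_d, params$L_m, params$D_d, params$h, k)
  qc <- character(0)
  if (any(sbp <= dbp)) qc <- c(qc, "SBP <= DBP in at least one estimate")
  if (any(c(sbp, dbp) < 20 | c(sbp, dbp) > 300)) {
    qc <- c(qc, "estimate outside the 20-300 mmHg physiological envelope")
  }
  transit_qc <- if (inherits(ptt, "vbp_transit")) ptt$qc else character(0)
  structure(
    tibble(sbp_mmHg = sbp, dbp_mmHg = dbp, ptt_s = ptt_s, ptt_d = ptt_d,
           pwv_s = params$L_m / ptt_s, pwv_d = params$L_m / ptt_d,
           variant = params$variant, L_m = params$L_m, D_s = params$D_s,
           D_d = params$D_d, h = params$h),
    constants = k, qc = c(transit_qc, qc),
    class = c("vbp_bp", class(tibble())))
}

#' Transit time implied by a blood pressure (closed-form inversion)
#'
#' The algebraic rearrangement of the pressure model:
#' `PTT = L * sqrt(rho * D / (h * E0)) * exp(-alpha * BP / 2)`.
#' [estimate_bp()] composed with this inversion is the identity to machine
#' precision, which makes it both the test oracle for the forward model and
#' the engine behind model-consistent synthetic cohorts.
#'
#' @param bp_mmHg blood pressure (vectorised).
#' @param params a `vbp_params` (single row or matching length).
#' @param branch `"systolic"` (uses `D_s`) or `"diastolic"` (uses `D_d`).
#' @return Transit time(s) in seconds.
#' @export
invert_ptt <- function(bp_mmHg, params, branch = c("systolic", "diastolic")) {
  branch <- match.arg(branch)
  stopifnot(inherits(params, "vbp_params"))
  k <- attr(params, "constants")
  D <- if (branch == "systolic") params$D_s else params$D_d
  params$L_m * sqrt(k$rho * D / (params$h * k$E0)) * exp(-k$alpha * bp_mmHg / 2)
}

#' Serialize a blood-pressure estimate to JSON
#'
#' @param bp a `vbp_bp`.
#' @param path output file; `NULL` returns the JSON string.
#' @param subject_id optional identifier embedded in the record.
#' @export
write_bp_json <- function(bp, path = NULL, subject_id = NULL) {
  stopifnot(inherits(bp, "vbp_bp"))
  k <- attr(bp, "constants")
  rec <- list(subject_id = subject_id, variant = bp$variant[1],
              sbp_mmHg = bp$sbp_mmHg, dbp_mmHg = bp$dbp_mmHg,
              ptt_s = bp$ptt_s, ptt_d = bp$ptt_d,
              pwv_s = bp$pwv_s, pwv_d = bp$pwv_d,
              L_m = bp$L_m, D_s = bp$D_s, D_d = bp$D_d, h = bp$h,
              constants = list(rho = k$rho, E0 = k$E0, alpha = k$alpha),
              qc = attr(bp, "qc"))
  if (is.null(path)) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
  }
}
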