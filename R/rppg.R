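#' Spatially averaged RGB trace over a region of interest
#'
#' For each requested frame the R, G and B channels are averaged over the
#' pixels whose (0-based) centres fall inside the ROI polygon. Masks are
#' memoised per distinct polygon so static-layout clips rasterise once.
#'
#' @param video a [vbp_video()].
#' @param rois a single `vbp_roi` (static ROI reused for every frame) or a
#'   list of `vbp_roi` objects, one per requested frame.
#' @param frame_indices 0-based frames to sample; defaults to every frame
#'   (or to the ROI's own frame indices when `rois` is a list).
#' @param site site label stored on the trace (`"face"` or `"hand"`).
#' @return A `vbp_trace` tibble with columns `frame_index`, `t`, `r`, `g`,
#'   `b` and attributes `fs` and `site`.
#' @export
mean_rgb_trace <- function(video, rois, frame_indices = NULL, site = "face") {
  stopifnot(inherits(video, "vbp_video"))
  if (inherits(rois, "vbp_roi")) {
    if (is.null(frame_indices)) frame_indices <- seq_len(video$frame_count) - 1L
    rois <- rep(list(rois), length(frame_indices))
  } else {
    stopifnot(is.list(rois), all(vapply(rois, inherits, logical(1), "vbp_roi")))
    if (is.null(frame_indices)) {
      frame_indices <- vapply(rois, function(r) r$frame_index, integer(1))
    }
  }
  stopifnot(length(rois) == length(frame_indices))

  mask_cache <- new.env(parent = emptyenv())
  out <- matrix(NA_real_, nrow = length(frame_indices), ncol = 3L)
  for (k in seq_along(frame_indices)) {
    fi <- frame_indices[k]
    frame <- video$frames[[fi + 1L]]
    mask <- roi_mask(rois[[k]]$vertices, video$width, video$height, mask_cache)
    if (length(mask$idx) == 0L) {
      abort(sprintf("ROI at frame %d contains no pixels", fi),
            class = "videobp_quality_error")
    }
    npix <- video$height * video$width
    out[k, ] <- c(mean(frame[mask$idx]),
                  mean(frame[mask$idx + npix]),
                  mean(frame[mask$idx + 2L * npix]))
  }
  structure(
    tibble(frame_index = as.integer(frame_indices),
           t = frame_indices / video$fps,
           r = out[, 1], g = out[, 2], b = out[, 3]),
    fs = video$fps, site = site,
    class = c("vbp_trace", class(tibble())))
}

# Linear indices (into a height x width matrix) of pixels whose 0-based
# centres lie inside the polygon. Cached by vertex coordinates.
roi_mask <- function(vertices, width, height, cache) {
  key <- paste(format(vertices, digits = 17), collapse = ",")
  hit <- get0(key, envir = cache)
  if (!is.null(hit)) return(hit)
  xr <- range(vertices[, 1]); yr <- range(vertices[, 2])
  xs <- max(0L, floor(xr[1])):min(width - 1L, ceiling(xr[2]))
  ys <- max(0L, floor(yr[1])):min(height - 1L, ceiling(yr[2]))
  grid <- expand.grid(x = xs, y = ys)
  inside <- pracma::inpolygon(grid$x, grid$y, vertices[, 1], vertices[, 2],
                              boundary = TRUE)
  idx <- (grid$x[inside]) * height + grid$y[inside] + 1L  # column-major, y = row
  res <- list(idx = idx)
  assign(key, res, envir = cache)
  res
}

#' Resample a trace onto a uniform time grid
#'
#' Frames dropped by quality control leave holes in the RGB trace; each
#' channel is linearly interpolated back onto the nominal frame grid so the
#' signal stays uniformly sampled at `fs` (a prerequisite for filtering and
#' for reading transit times off sample indices). Leading/trailing missing
#' frames are filled by edge replication.
#'
#' @param trace a `vbp_trace`.
#' @param frame_count total frames of the source clip; defaults to spanning
#'   the observed frame indices.
#' @return A `vbp_trace` on the full uniform grid.
#' @export
regularize_trace <- function(trace, frame_count = NULL) {
  fs <- attr(trace, "fs")
  if (is.null(frame_count)) frame_count <- max(trace$frame_index) + 1L
  grid <- seq_len(frame_count) - 1L
  interp <- function(v) {
    approx(trace$frame_index, v, xout = grid, method = "linear", rule = 2)$y
  }
  structure(
    tibble(frame_index = as.integer(grid), t = grid / fs,
           r = interp(trace$r), g = interp(trace$g), b = interp(trace$b)),
    fs = fs, site = attr(trace, "site"),
    class = c("vbp_trace", class(tibble())))
}

#' Chrominance-based pulse extraction (CHROM)
#'
#' Projects the mean-RGB trace onto two chrominance axes to recover the
#' blood-volume pulse while cancelling common-mode intensity changes
#' (illumination flicker, shadows). In each sliding window the channels are
#' normalised by their window means, combined as `X = 3R - 2G` and
#' `Y = 1.5R + G - 1.5B`, and mixed as `S = X - (sd(X)/sd(Y)) Y`; windows are
#' Hann-weighted and overlap-added, with the accumulated window weight
#' divided out so the envelope is flat. The output is zero-mean and, by
#' construction of the mean normalisation, exactly invariant to scaling all
#' three channels by a common positive constant.
#'
#' A constant (zero-variance) trace carries no pulsatile component; the
#' function then returns an all-zero signal with a warning rather than
#' failing, so quality control can report the condition.
#'
#' @param trace a `vbp_trace` (uniformly sampled; see [regularize_trace()]).
#' @param window_s sliding window length in seconds (default 1.6 s).
#' @param overlap fractional window overlap (default 0.5).
#' @return A `vbp_ppg` tibble with columns `t`, `value` and attributes `fs`
#'   and `site`.
#' @export
chrom_extract <- function(trace, window_s = 1.6, overlap = 0.5) {
  fs <- attr(trace, "fs")
  n <- nrow(trace)
  win <- max(4L, round(window_s * fs))
  if (n < win) {
    abort(sprintf("trace too short for CHROM: %d samples < one %g s window",
                  n, window_s), class = "videobp_input_error")
  }
  R <- trace$r; G <- trace$g; B <- trace$b
  if (sd(R) == 0 && sd(G) == 0 && sd(B) == 0) {
    warn("no pulsatile component: constant RGB trace, returning zero signal")
    return(new_ppg(rep(0, n), fs, attr(trace, "site")))
  }
  hop <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, n - win + 1L, by = hop)
  if (tail(starts, 1L) + win - 1L < n) starts <- c(starts, n - win + 1L)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  out <- numeric(n); wsum <- numeric(n)
  for (s0 in starts) {
    idx <- s0:(s0 + win - 1L)
    rn <- safe_norm(R[idx]); gn <- safe_norm(G[idx]); bn <- safe_norm(B[idx])
    X <- 3 * rn - 2 * gn
    Y <- 1.5 * rn + gn - 1.5 * bn
    X <- X - mean(X); Y <- Y - mean(Y)
    sy <- sd(Y)
    alpha <- if (sy > 0) sd(X) / sy else 0
    S <- X - alpha * Y
    out[idx] <- out[idx] + hann * S
    wsum[idx] <- wsum[idx] + hann
  }
  wsum[wsum == 0] <- 1
  s <- out / wsum
  s <- s - mean(s)
  # The chrominance projection is orientation-ambiguous (its sign depends on
  # the per-channel pulsatile ratios). Orient so the sharp systolic peaks
  # point upward: a pulse waveform sits mostly near its diastolic baseline,
  # so the correctly oriented signal has positive skewness.
  if (sd(s) > 0 && mean(s^3) < 0) s <- -s
  new_ppg(s, fs, attr(trace, "site"))
}

safe_norm <- function(x) {
  m <- mean(x)
  if (m == 0) rep(1, length(x)) else x / m
}

#' Wrap raw samples as a pulse signal
#'
#' @param values numeric samples (arbitrary units).
#' @param fs sampling rate, Hz.
#' @param site site label (`"face"` or `"hand"`).
#' @return A `vbp_ppg` tibble with columns `t`, `value`.
#' @export
ppg_signal <- function(values, fs, site = "face") {
  stopifnot(is.numeric(values), fs > 0)
  structure(
    tibble(t = (seq_along(values) - 1) / fs, value = as.numeric(values)),
    fs = fs, site = site,
    class = c("vbp_ppg", class(tibble())))
}

new_ppg <- function(values, fs, site) ppg_signal(values, fs, site)

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (defaults 0.25-15 Hz, total order 4)
#' forward and backward (`signal::filtfilt`), so the filter contributes no
#' group delay: pulse transit time is a timing measurement and a causal
#' filter's delay would bias it unless it cancelled exactly between sites.
#' Both sites are filtered with one shared design in the pipeline.
#'
#' The 15 Hz upper cutoff requires `fs > 30`; at the 30 fps capture minimum
#' it sits exactly at Nyquist, so when `high >= fs/2` the cutoff is clipped
#' to `0.45 fs` with a warning (or, with `auto_clip = FALSE`, an error
#' telling the caller to lower the cutoff or raise the frame rate).
#'
#' @param ppg a `vbp_ppg`.
#' @param low,high cutoff frequencies in Hz.
#' @param order total band-pass filter order (even; default 4).
#' @param auto_clip clip an infeasible `high` to `0.45 fs` instead of
#'   erroring.
#' @return A zero-mean `vbp_ppg`.
#' @export
bandpass <- function(ppg, low = 0.25, high = 15, order = 4, auto_clip = TRUE) {
  fs <- attr(ppg, "fs")
  stopifnot(low > 0, high > low, order %% 2 == 0)
  if (high >= fs / 2) {
    if (auto_clip) {
      high <- 0.45 * fs
      warn(sprintf("high cutoff >= Nyquist; clipped to %.3g Hz (fs = %g)", high, fs))
    } else {
      abort(sprintf(
        "high cutoff %g Hz >= Nyquist (fs/2 = %g Hz): lower the cutoff or raise fs",
        high, fs / 2), class = "videobp_input_error")
    }
  }
  flt <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  # demean first: the DC step at the signal edges is the dominant source of
  # forward-backward edge transients (a constant input then maps to zero)
  y <- signal::filtfilt(flt, ppg$value - mean(ppg$value))
  new_ppg(y - mean(y), fs, attr(ppg, "site"))
}

#' Export a signal as a two-column CSV
#'
#' @param ppg a `vbp_ppg`.
#' @param path output file (`time_s,value`).
#' @export
write_signal_csv <- function(ppg, path) {
  readr::write_csv(tibble(time_s = ppg$t, value = ppg$value), path)
  invisible(path)
}

#' @export
autoplot.vbp_ppg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::labs(x = "time (s)", y = "pulse (a.u.)",
                  title = sprintf("rPPG signal (%s)", attr(object, "site") %||% "")) +
    ggplot2::theme_minimal()
}
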