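#' In-memory video clip
#'
#' A light container for a sequence of RGB frames sampled at a fixed frame
#' rate. Frames are numeric arrays `height x width x 3` with 8-bit channel
#' values on `[0, 255]`. Pixel coordinates are 0-based with the origin at the
#' top-left corner, x increasing rightward and y downward; frame indices are
#' 0-based so they round-trip through the JSON-lines landmark interchange
#' format unchanged.
#'
#' The minimum capture conditions for reliable pulse extraction are 30
#' frames/s and 320 x 240 px. `validate_video()` enforces them as hard errors
#' in strict mode and as warnings otherwise, so that deliberately small
#' synthetic clips can flow through the pipeline in tests.
#'
#' @param frames list of `height x width x 3` numeric arrays on `[0, 255]`.
#' @param fps frames per second (> 0).
#' @return A `vbp_video` object (list with elements `frames`, `fps`,
#'   `frame_count`, `width`, `height`).
#' @examples
#' f <- array(128, dim = c(24, 32, 3))
#' v <- vbp_video(list(f, f, f), fps = 60)
#' v$frame_count
#' @export
vbp_video <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0L) {
    abort("empty video: at least one frame is required", class = "videobp_input_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort("fps must be a single positive number", class = "videobp_input_error")
  }
  dims <- dim(frames[[1L]])
  if (length(dims) != 3L || dims[3L] != 3L) {
    abort("frames must be height x width x 3 arrays", class = "videobp_input_error")
  }
  same <- vapply(frames, function(f) identical(dim(f), dims), logical(1))
  if (!all(same)) {
    abort(sprintf("all frames must share dimensions; frame %d differs",
                  which(!same)[1L] - 1L), class = "videobp_input_error")
  }
  structure(
    list(frames = frames, fps = fps, frame_count = length(frames),
         height = dims[1L], width = dims[2L]),
    class = "vbp_video"
  )
}

#' @export
print.vbp_video <- function(x, ...) {
  cat(sprintf("<vbp_video> %d frames, %d x %d px, %.6g fps (%.2f s)\n",
              x$frame_count, x$width, x$height, x$fps, x$frame_count / x$fps))
  invisible(x)
}

#' Check a video against minimum capture requirements
#'
#' @param video a [vbp_video()].
#' @param min_fps,min_width,min_height minimum capture conditions.
#' @param strict if `TRUE` violations are errors, otherwise warnings.
#' @return `video`, invisibly.
#' @export
validate_video <- function(video, min_fps = 30, min_width = 320,
                           min_height = 240, strict = TRUE) {
  stopifnot(inherits(video, "vbp_video"))
  problems <- character(0)
  if (video$fps < min_fps) {
    problems <- c(problems, sprintf("frame rate %.3g fps below minimum %g fps",
                                    video$fps, min_fps))
  }
  if (video$width < min_width || video$height < min_height) {
    problems <- c(problems,
                  sprintf("resolution %d x %d below minimum %d x %d",
                          video$width, video$height, min_width, min_height))
  }
  if (length(problems)) {
    msg <- paste(problems, collapse = "; ")
    if (strict) abort(msg, class = "videobp_input_error") else warn(msg)
  }
  invisible(video)
}

#' Read and write videos as PNG frame directories
#'
#' Clips are stored on disk as a directory of zero-padded PNG frames
#' (`frame_000000.png`, ...) plus a `meta.json` sidecar holding the frame
#' rate, a plain-text representation that survives any toolchain.
#'
#' The blood-volume pulse modulates skin colour by far less than one 8-bit
#' grey level, so plain quantisation would erase it from a synthetic clip.
#' Frames are therefore written with a static spatial dither (a fixed
#' sub-level offset pattern per pixel position, `dither = TRUE`): each
#' pixel flips its quantised value at a slightly different signal level, so
#' the spatial mean over a region of interest resolves amplitudes far below
#' one level — the standard dithered-quantisation argument. The pattern is
#' a pure function of pixel position, keeping writes deterministic.
#'
#' @param video a [vbp_video()].
#' @param path directory to create/read.
#' @param dither apply the static spatial dither before 8-bit quantisation.
#' @return `write_video_frames()` returns `path` invisibly;
#'   `read_video_frames()` returns a [vbp_video()].
#' @export
write_video_frames <- function(video, path, dither = TRUE) {
  stopifnot(inherits(video, "vbp_video"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- if (dither) {
    dither_pattern(video$height, video$width)
  } else {
    array(0, dim = c(video$height, video$width, 3L))
  }
  for (i in seq_len(video$frame_count)) {
    f <- (video$frames[[i]] + d) / 255
    f[f < 0] <- 0; f[f > 1] <- 1
    png::writePNG(f, file.path(path, sprintf("frame_%06d.png", i - 1L)))
  }
  jsonlite::write_json(list(fps = video$fps, frame_count = video$frame_count),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

# Deterministic sub-level offset in (-0.5, 0.5) per pixel position and
# channel, from a small integer hash; period-free enough at ROI scale.
dither_pattern <- function(height, width) {
  y <- matrix(seq_len(height) - 1L, height, width)
  x <- matrix(seq_len(width) - 1L, height, width, byrow = TRUE)
  d <- array(0, dim = c(height, width, 3L))
  for (c in 1:3) {
    d[, , c] <- (((x * 37L + y * 61L + c * 29L) %% 101L) + 0.5) / 101 - 0.5
  }
  d
}

#' @rdname write_video_frames
#' @export
read_video_frames <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("no meta.json under '%s'", path), class = "videobp_input_error")
  }
  meta <- jsonlite::read_json(meta_path)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0L) {
    abort("empty video: no frame PNGs found", class = "videobp_input_error")
  }
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    a[, , 1:3, drop = FALSE] * 255
  })
  vbp_video(frames, fps = meta$fps)
}
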