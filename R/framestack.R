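#' Frame stack: the pipeline's working representation of a recording
#'
#' A `frame_stack` holds an ordered grayscale frame sequence as a 3-D numeric
#' array indexed `(time, row, col)` with intensities on the normalized
#' `[0, 1]` scale, together with per-frame acquisition times in seconds and
#' the nominal frame rate. All pipeline stages consume and produce this type,
#' so gain/offset parameters are independent of the source bit depth.
#'
#' @param frames 3-D numeric array `(time, row, col)`, values in `[0, 1]`.
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing, one per frame. Default: synthesized as `(i - 1) / fps`.
#' @param fps Nominal frames per second (> 0). Required when `times` is NULL.
#' @param source_bit_depth Integer bit depth of the source data (8 or 16).
#'
#' @return An object of class `frame_stack` with fields `frames`, `times`,
#'   `fps` and `source_bit_depth`.
#' @examples
#' fs <- frame_stack(array(runif(5 * 8 * 8), c(5, 8, 8)), fps = 1)
#' n_frames(fs)
#' @export
frame_stack <- function(frames, times = NULL, fps = NULL,
                        source_bit_depth = 8L) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array indexed (time, row, col)", call. = FALSE)
  }
  storage.mode(frames) <- "double"
  if (anyNA(frames) || any(!is.finite(frames))) {
    stop("frame intensities must all be finite", call. = FALSE)
  }
  if (min(frames) < 0 || max(frames) > 1) {
    stop("frame intensities must lie in [0, 1]; rescale before constructing",
         call. = FALSE)
  }
  nt <- dim(frames)[1L]
  if (is.null(times)) {
    if (is.null(fps)) {
      stop("supply `fps` (or explicit `times`): the stack needs a time base",
           call. = FALSE)
    }
    times <- (seq_len(nt) - 1) / fps
  }
  if (length(times) != nt) {
    stop(sprintf("length(times) [%d] must equal the frame count [%d]",
                 length(times), nt), call. = FALSE)
  }
  if (nt > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (is.null(fps)) {
    fps <- if (nt > 1L) 1 / stats::median(diff(times)) else 1
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (!source_bit_depth %in% c(8L, 16L)) {
    stop("`source_bit_depth` must be 8 or 16", call. = FALSE)
  }
  structure(
    list(frames = frames, times = as.numeric(times), fps = as.numeric(fps),
         source_bit_depth = as.integer(source_bit_depth)),
    class = "frame_stack"
  )
}

#' @rdname frame_stack
#' @param x A `frame_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  dim(x$frames)[1L]
}

#' @rdname frame_stack
#' @export
frame_shape <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  dim(x$frames)[2:3]
}

#' Extract one frame as a matrix
#' @param x A `frame_stack`.
#' @param i Frame index (1-based).
#' @return A `(row, col)` numeric matrix.
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "frame_stack"))
  if (i < 1L || i > n_frames(x)) {
    stop(sprintf("frame index %d out of range [1, %d]", i, n_frames(x)),
         call. = FALSE)
  }
  matrix(x$frames[i, , ], frame_shape(x)[1L], frame_shape(x)[2L])
}

#' Replace the frame data of a stack, keeping its time base
#' @param x A `frame_stack`.
#' @param frames New 3-D frame array with the same leading dimension.
#' @return A `frame_stack`.
#' @keywords internal
set_frames <- function(x, frames) {
  frame_stack(frames, times = x$times, fps = x$fps,
              source_bit_depth = x$source_bit_depth)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, %.4g fps, t = [%.3g, %.3g] s, %d-bit source\n",
    d[1L], d[2L], d[3L], x$fps, x$times[1L], x$times[d[1L]],
    x$source_bit_depth))
  invisible(x)
}

#' Validate an RGB frame
#'
#' RGB frames are `(row, col, 3)` numeric arrays with all values finite and in
#' `[0, 1]`; they are the render target for trail images and videos.
#'
#' @param pixels Candidate array.
#' @return The validated array, invisibly classed `rgb_frame`.
#' @export
rgb_frame <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("an RGB frame must be a (row, col, 3) array", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels)) ||
      min(pixels) < 0 || max(pixels) > 1) {
    stop("RGB frame values must be finite and in [0, 1]", call. = FALSE)
  }
  structure(pixels, class = c("rgb_frame", class(pixels)))
}

#' Promote a grayscale matrix to a 3-channel RGB array
#' @param m A numeric matrix in `[0, 1]`.
#' @return A `(row, col, 3)` array.
#' @export
gray_to_rgb <- function(m) {
  stopifnot(is.matrix(m))
  array(rep(m, 3L), c(dim(m), 3L))
}

#' Quantize intensities to the 8-bit grid
#'
#' Maps values in `[0, 1]` to the nearest of the 256 representable 8-bit
#' levels (`k / 255`). Applied before lossless output so that a write/read
#' round trip is bit-identical.
#'
#' @param x Numeric array in `[0, 1]`.
#' @return Array of the same shape on the 8-bit grid.
#' @export
quantize_8bit <- function(x) {
  round(pmin(pmax(x, 0), 1) * 255) / 255
}

`%||%` <- function(a, b) if (is.null(a)) b else a
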