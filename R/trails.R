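#' Trail rendering parameters
#'
#' All knobs of the visualization stage. Defaults are this package's own:
#' gain 10, offset 0.05, fade fraction 0.2, 20 s window, `blue_red` map.
#'
#' @param window_s Temporal window length in seconds, or `"full"` for a
#'   single projection over the whole recording.
#' @param fade_fraction Fraction of the window (in `[0, 0.5]`) over which the
#'   oldest track segments ramp linearly to invisibility; 0 disables fading.
#' @param gain Contrast gain (> 0) applied to the average-subtracted frames.
#' @param offset Noise floor in `[0, 1)`: pixels with `gain * v <= offset`
#'   render black, removing low-amplitude sensor noise.
#' @param colormap A `trail_colormap`, built-in name, or colormap file path.
#' @param stride Emit every `stride`-th input frame in video mode (>= 1).
#' @param global_time In video mode, color by time within the whole recording
#'   instead of within each window (default FALSE: window-relative recency).
#' @return A `trail_params` list.
#' @export
trail_params <- function(window_s = 20, fade_fraction = 0.2, gain = 10,
                         offset = 0.05, colormap = "blue_red", stride = 1L,
                         global_time = FALSE) {
  if (!identical(window_s, "full") &&
      (!is.numeric(window_s) || window_s <= 0)) {
    stop("`window_s` must be a positive number of seconds or \"full\"",
         call. = FALSE)
  }
  if (!is.numeric(fade_fraction) || fade_fraction < 0 || fade_fraction > 0.5) {
    stop("`fade_fraction` must lie in [0, 0.5]", call. = FALSE)
  }
  if (!is.numeric(gain) || gain <= 0) {
    stop("`gain` must be positive", call. = FALSE)
  }
  if (!is.numeric(offset) || offset < 0 || offset >= 1) {
    stop("`offset` must lie in [0, 1)", call. = FALSE)
  }
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) {
    stop("`stride` must be an integer >= 1", call. = FALSE)
  }
  structure(list(window_s = window_s, fade_fraction = fade_fraction,
                 gain = gain, offset = offset,
                 colormap = resolve_colormap(colormap), stride = stride,
                 global_time = isTRUE(global_time)),
            class = "trail_params")
}

#' Contrast gain and noise-floor offset
#'
#' Pixelwise `min(1, max(0, gain * v - offset))`. Scaling enhances the faint
#' average-subtracted signal; the fixed offset removes low-amplitude noise,
#' sending any pixel with `gain * v <= offset` to exactly 0.
#'
#' @param frame 2-D numeric array in `[0, 1]`.
#' @param gain Gain (> 0).
#' @param offset Offset in `[0, 1)`.
#' @return Matrix of the same shape in `[0, 1]`.
#' @export
enhance <- function(frame, gain, offset) {
  if (!is.numeric(gain) || gain <= 0) stop("`gain` must be positive",
                                           call. = FALSE)
  if (!is.numeric(offset) || offset < 0 || offset >= 1) {
    stop("`offset` must lie in [0, 1)", call. = FALSE)
  }
  pmin(pmax(gain * frame - offset, 0), 1)
}

#' Fade weight of a frame within a window
#'
#' With `m = round(fade_fraction * n)`, the oldest `m` frames of the window
#' ramp linearly from weight 0 (oldest, invisible) to full weight, so old
#' track segments gradually disappear across successive output frames rather
#' than stopping abruptly. Only the old end fades: the newest frame always
#' carries weight 1, so the worm's current position never dims. With
#' `fade_fraction = 0` all weights are 1.
#'
#' @param i Frame index within the window, 0-based (0 = oldest); vectorized.
#' @param n Window length in frames.
#' @param fade_fraction Fraction in `[0, 0.5]`.
#' @return Weights in `[0, 1]`, nondecreasing in `i`.
#' @export
fade_weight <- function(i, n, fade_fraction) {
  if (fade_fraction < 0 || fade_fraction > 0.5) {
    stop("`fade_fraction` must lie in [0, 0.5]", call. = FALSE)
  }
  if (any(i < 0 | i >= n)) {
    stop(sprintf("frame index out of range [0, %d)", n), call. = FALSE)
  }
  m <- round(fade_fraction * n)
  if (m < 1) return(rep(1, length(i)))
  ifelse(i < m, i / m, 1)
}

#' Apply time color and fade weight to an enhanced frame
#'
#' Output channel `c` is `frame * evaluate_colormap(map, u)[c] * weight`.
#'
#' @param enh_frame Enhanced 2-D array in `[0, 1]`.
#' @param u Normalized time in `[0, 1]`.
#' @param map A `trail_colormap`.
#' @param weight Fade weight in `[0, 1]`.
#' @return A `(row, col, 3)` RGB array.
#' @export
colorize <- function(enh_frame, u, map, weight = 1) {
  if (weight < 0 || weight > 1) stop("`weight` must lie in [0, 1]",
                                     call. = FALSE)
  rgb <- evaluate_colormap(map, u)[1L, ]
  base <- enh_frame * weight
  out <- array(0, c(dim(enh_frame), 3L))
  for (ch in 1:3) out[, , ch] <- base * rgb[ch]
  out
}

new_trail_frame <- function(image, t_end, window) {
  structure(list(image = image, t_end = t_end, window = window),
            class = "trail_frame")
}

#' @export
print.trail_frame <- function(x, ...) {
  cat(sprintf("<trail_frame> %d x %d px, window [%.3g, %.3g] s\n",
              dim(x$image)[1L], dim(x$image)[2L], x$window[1L], x$window[2L]))
  invisible(x)
}

#' Windowed maximum projection with time-to-color encoding
#'
#' Collapses a contiguous range of average-subtracted frames into one trail
#' image. Each frame is enhanced ([enhance()]) and weighted by its fade
#' weight; per pixel, the frame with the largest weighted enhanced intensity
#' wins (ties broken toward the LATER frame, emphasizing recent behavior),
#' and the output pixel is that frame's enhanced value multiplied by the
#' color at its normalized window time `u = (i - first) / (last - first)`
#' (`u = 1` for a one-frame window) and its weight. Selection is by scalar
#' intensity with color applied afterwards, never a per-channel max, so
#' colors from different times never blend into nonexistent hues. Pixels
#' where every weighted intensity is 0 render black.
#'
#' @param sub_stack A [frame_stack] of average-subtracted frames.
#' @param frame_indices Contiguous 1-based frame range.
#' @param params A [trail_params].
#' @param u_range Optional `c(u_first, u_last)` overriding the normalized
#'   times assigned to the window ends (used for global-time coloring).
#' @return A `trail_frame` with fields `image`, `t_end`, `window`.
#' @export
project_window <- function(sub_stack, frame_indices, params,
                           u_range = NULL) {
  stopifnot(inherits(sub_stack, "frame_stack"),
            inherits(params, "trail_params"))
  idx <- as.integer(frame_indices)
  if (length(idx) == 0L) stop("empty frame range", call. = FALSE)
  if (any(diff(idx) != 1L)) stop("frame range must be contiguous",
                                 call. = FALSE)
  if (idx[1L] < 1L || idx[length(idx)] > n_frames(sub_stack)) {
    stop(sprintf("frame range [%d, %d] outside stack [1, %d]",
                 idx[1L], idx[length(idx)], n_frames(sub_stack)),
         call. = FALSE)
  }
  n <- length(idx)
  u <- if (!is.null(u_range)) {
    if (n == 1L) u_range[2L]
    else u_range[1L] + (seq_len(n) - 1) / (n - 1) * diff(u_range)
  } else if (n == 1L) 1 else (seq_len(n) - 1) / (n - 1)
  w <- fade_weight(seq_len(n) - 1L, n, params$fade_fraction)

  shp <- frame_shape(sub_stack)
  best <- matrix(0, shp[1L], shp[2L])       # best weighted intensity so far
  best_enh <- matrix(0, shp[1L], shp[2L])   # winning frame's enhanced value
  best_u <- matrix(0, shp[1L], shp[2L])
  best_w <- matrix(0, shp[1L], shp[2L])
  for (k in seq_len(n)) {
    enh <- enhance(get_frame(sub_stack, idx[k]), params$gain, params$offset)
    s <- enh * w[k]
    take <- s >= best & s > 0   # >= : later frame wins ties
    if (any(take)) {
      best[take] <- s[take]
      best_enh[take] <- enh[take]
      best_u[take] <- u[k]
      best_w[take] <- w[k]
    }
  }
  rgb_u <- evaluate_colormap(params$colormap, as.vector(best_u))
  image <- array(0, c(shp, 3L))
  lit <- best > 0
  base <- best_enh * best_w
  for (ch in 1:3) {
    plane <- matrix(0, shp[1L], shp[2L])
    plane[lit] <- base[lit] * matrix(rgb_u[, ch], shp[1L], shp[2L])[lit]
    image[, , ch] <- plane
  }
  new_trail_frame(image, t_end = sub_stack$times[idx[n]],
                  window = c(sub_stack$times[idx[1L]],
                             sub_stack$times[idx[n]]))
}

#' Render a full-recording trail still
#'
#' Projects the whole (average-subtracted) recording into one image;
#' normalized time `u` spans recording start to end, so with a sequential
#' map the full positional history reads as a single temporal gradient
#' (early path in the start color, late path in the end color).
#'
#' @param stack A [frame_stack] of average-subtracted frames.
#' @param params A [trail_params]; `window_s` is treated as `"full"`.
#' @return A `trail_frame`.
#' @export
render_still <- function(stack, params = trail_params(window_s = "full")) {
  project_window(stack, seq_len(n_frames(stack)), params)
}

#' Render a sliding-window trail video
#'
#' Applies the windowed projection within a moving temporal window across the
#' recording: for each output time `t` (every `stride`-th input frame) the
#' window is the trailing `n = round(window_s * fps)` frames intersected with
#' the recording (shorter at the start; never padded). Each output frame thus
#' shows only the recent paths taken. By default `u` is normalized within
#' each window (recency coloring); with `global_time` the recording-wide time
#' is used instead.
#'
#' @param stack A [frame_stack] of average-subtracted frames.
#' @param params A [trail_params] with numeric `window_s`.
#' @return List of `trail_frame`s, ordered by output time.
#' @export
render_video <- function(stack, params = trail_params()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(params, "trail_params"))
  nt <- n_frames(stack)
  if (identical(params$window_s, "full")) {
    stop("`window_s` must be numeric for video mode; use render_still() for a full projection",
         call. = FALSE)
  }
  n <- round(params$window_s * stack$fps)
  if (n < 1L) stop("window shorter than one frame interval", call. = FALSE)
  if (n > nt) {
    warning(sprintf(
      "window of %d frames exceeds the %d-frame recording; emitting a single full-recording trail frame",
      n, nt))
    return(list(project_window(stack, seq_len(nt), params)))
  }
  out_idx <- seq(1L, nt, by = params$stride)
  lapply(out_idx, function(t) {
    first <- max(1L, t - n + 1L)
    ur <- if (params$global_time && nt > 1L) {
      c((first - 1) / (nt - 1), (t - 1) / (nt - 1))
    } else NULL
    project_window(stack, first:t, params, u_range = ur)
  })
}
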