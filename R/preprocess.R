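#' Per-frame brightness normalization
#'
#' The first preprocessing stage: each frame is rescaled multiplicatively so
#' that its mean intensity equals a common target, removing global flicker
#' (lamp drift, auto-exposure) before vignetting correction. With
#' `target = "auto"` the target is the grand mean of the per-frame means, so
#' the overall brightness of the recording is preserved.
#'
#' @param stack A [frame_stack]; every frame must have strictly positive mean.
#' @param target Common mean intensity in `[0, 1]`, or `"auto"`.
#' @return A [frame_stack] whose per-frame means equal `target`
#'   (up to `[0, 1]` clipping).
#' @export
normalize_brightness <- function(stack, target = "auto") {
  stopifnot(inherits(stack, "frame_stack"))
  means <- apply(stack$frames, 1L, mean)
  bad <- which(means <= 0)
  if (length(bad)) {
    stop(sprintf("frame %d has zero mean intensity and cannot be rescaled",
                 bad[1L]), call. = FALSE)
  }
  if (identical(target, "auto")) {
    target <- mean(means)
  } else if (!is.numeric(target) || length(target) != 1L ||
             target <= 0 || target > 1) {
    stop("`target` must be \"auto\" or a number in (0, 1]", call. = FALSE)
  }
  out <- stack$frames * (target / means)   # recycles along dim 1
  set_frames(stack, clip01(out))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Temporal mean image of a recording
#'
#' @param stack A [frame_stack] with at least 2 frames.
#' @return An `average_frame`: list with `pixels` (a `(row, col)` matrix in
#'   `[0, 1]`) and `n_frames`.
#' @export
compute_average_frame <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- n_frames(stack)
  if (nt < 2L) {
    stop("need at least 2 frames to form a meaningful average", call. = FALSE)
  }
  px <- colMeans(stack$frames)   # mean over dim 1 -> (row, col) matrix
  structure(list(pixels = px, n_frames = nt), class = "average_frame")
}

#' @export
print.average_frame <- function(x, ...) {
  cat(sprintf("<average_frame> %d x %d px, mean of %d frames\n",
              nrow(x$pixels), ncol(x$pixels), x$n_frames))
  invisible(x)
}

# Separable Gaussian blur realized as banded-matrix multiplication
# K_r %*% X %*% t(K_c); exact (no FFT), kernel truncated at 4 sigma and
# renormalized, so a constant image blurs to itself to machine precision.
#
# Boundary handling matters here far more than in ordinary smoothing: the
# blur sigma for vignette estimation is a substantial fraction of the frame,
# so the boundary rule's bias penetrates sigma-deep into the field. Mirror
# reflection flips the sign of the illumination gradient at the edge; the
# blur rounds that kink and the resulting bias dominates the corrected
# image's residual flatness. The default "extrapolate" rule instead extends
# the image antisymmetrically about the edge sample (g(n + t) =
# 2 g(n) - g(n - t)), which preserves both the edge value and the edge
# slope, is exact for linear illumination ramps, and introduces no dark
# halo. "reflect" (half-sample mirror, scipy's default) is kept as an
# option.
reflect_index <- function(p, n) {
  m <- (p - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

blur_matrix <- function(n, sigma, boundary = c("extrapolate", "reflect")) {
  boundary <- match.arg(boundary)
  r <- max(1L, ceiling(4 * sigma))
  if (boundary == "extrapolate") r <- min(n - 1L, r)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  add <- function(rows, cols, coef) {
    ij <- cbind(rows, cols)
    K[ij] <<- K[ij] + coef
  }
  for (d in -r:r) {
    wk <- w[d + r + 1L]
    p <- idx + d
    if (boundary == "reflect") {
      add(idx, reflect_index(p, n), wk)
      next
    }
    inside <- p >= 1L & p <= n
    if (any(inside)) add(idx[inside], p[inside], wk)
    lo <- p < 1L
    if (any(lo)) {
      add(idx[lo], rep(1L, sum(lo)), 2 * wk)
      add(idx[lo], 2L - p[lo], -wk)
    }
    hi <- p > n
    if (any(hi)) {
      add(idx[hi], rep(n, sum(hi)), 2 * wk)
      add(idx[hi], 2L * n - p[hi], -wk)
    }
  }
  K
}

#' Gaussian blur of a matrix
#'
#' Separable Gaussian smoothing with explicit boundary control.
#' `"extrapolate"` (default) extends the image antisymmetrically about each
#' edge sample, preserving the value and slope of the illumination profile
#' at the frame border; `"reflect"` is the conventional half-sample mirror.
#'
#' @param m Numeric matrix.
#' @param sigma_px Standard deviation in pixels (> 0).
#' @param boundary `"extrapolate"` or `"reflect"`.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma_px,
                          boundary = c("extrapolate", "reflect")) {
  stopifnot(is.matrix(m))
  if (sigma_px <= 0) stop("`sigma_px` must be positive", call. = FALSE)
  boundary <- match.arg(boundary)
  blur_matrix(nrow(m), sigma_px, boundary) %*% m %*%
    t(blur_matrix(ncol(m), sigma_px, boundary))
}

#' Estimate the multiplicative vignette field from the average frame
#'
#' Vignetting (radially decreasing illumination) is modelled as a smooth
#' multiplicative field. The estimate is the Gaussian blur of the temporal
#' average frame -- blurred far beyond worm scale so that only low-frequency
#' brightness structure survives -- floored at `epsilon` to guard the
#' subsequent division in dark regions outside the plate, then divided by its
#' own spatial mean so the field has mean 1 and the correction preserves
#' global brightness.
#'
#' @param avg An `average_frame` from [compute_average_frame()].
#' @param sigma_px Blur standard deviation in pixels; default 1/8 of the
#'   smaller frame dimension ("low-frequency" means far beyond worm scale).
#' @param epsilon Positive floor applied before mean normalization
#'   (default 1e-3 on the `[0, 1]` scale).
#' @param boundary Blur boundary rule, see [gaussian_blur()].
#' @return A `vignette_field`: list with `field` (matrix, spatial mean 1,
#'   minimum >= epsilon), `sigma_px` and `epsilon`.
#' @export
estimate_vignette <- function(avg, sigma_px = NULL, epsilon = 1e-3,
                              boundary = c("extrapolate", "reflect")) {
  stopifnot(inherits(avg, "average_frame"))
  if (is.null(sigma_px)) sigma_px <- min(dim(avg$pixels)) / 8
  if (sigma_px <= 0) stop("`sigma_px` must be positive", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  f <- gaussian_blur(avg$pixels, sigma_px, boundary = match.arg(boundary))
  f <- pmax(f, epsilon)
  f <- f / mean(f)
  structure(list(field = f, sigma_px = sigma_px, epsilon = epsilon),
            class = "vignette_field")
}

#' @export
print.vignette_field <- function(x, ...) {
  cat(sprintf(
    "<vignette_field> %d x %d px, sigma %.3g px, range [%.4g, %.4g], mean %.6g\n",
    nrow(x$field), ncol(x$field), x$sigma_px, min(x$field), max(x$field),
    mean(x$field)))
  invisible(x)
}

#' Divide out the vignette field
#'
#' @param stack A [frame_stack].
#' @param field A `vignette_field` with matching spatial shape.
#' @return A [frame_stack], each frame divided pixelwise by the field and
#'   clipped to `[0, 1]`.
#' @export
correct_vignette <- function(stack, field) {
  stopifnot(inherits(stack, "frame_stack"), inherits(field, "vignette_field"))
  if (!identical(dim(field$field), frame_shape(stack))) {
    stop(sprintf("vignette field is %s but frames are %s",
                 paste(dim(field$field), collapse = "x"),
                 paste(frame_shape(stack), collapse = "x")), call. = FALSE)
  }
  d <- dim(stack$frames)
  div <- aperm(array(field$field, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  set_frames(stack, clip01(stack$frames / div))
}

#' Average-frame subtraction
#'
#' The second preprocessing stage: each frame is replaced by its absolute
#' difference from the stack's own temporal mean image, isolating pixels that
#' change in intensity over the recording. The absolute value makes the
#' operation identical for brightfield recordings (dark worms on bright agar)
#' and darkfield recordings (bright worms on dark background).
#'
#' @param stack A [frame_stack] with at least 2 frames.
#' @return A [frame_stack] of absolute differences, values in `[0, 1]`.
#' @export
average_subtract <- function(stack) {
  avg <- compute_average_frame(stack)   # validates >= 2 frames
  d <- dim(stack$frames)
  m <- aperm(array(avg$pixels, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  set_frames(stack, abs(stack$frames - m))
}

#' Run the full preprocessing chain
#'
#' Brightness normalization, then optional vignetting correction (the field
#' estimated from the normalized stack's average frame), then average
#' subtraction with the mean recomputed on the corrected stack -- so a
#' perfectly static scene maps to exactly zero.
#'
#' @param stack A [frame_stack].
#' @param normalize Apply per-frame brightness normalization (default TRUE).
#' @param target Brightness target, see [normalize_brightness()].
#' @param vignette Apply vignetting correction (default TRUE; an ideal imaging
#'   setup minimizes the need for it).
#' @param sigma_px,epsilon Vignette estimation parameters, see
#'   [estimate_vignette()].
#' @return List with `subtracted` (the average-subtracted [frame_stack]) and
#'   `vignette` (the `vignette_field` used, or NULL).
#' @export
preprocess_stack <- function(stack, normalize = TRUE, target = "auto",
                             vignette = TRUE, sigma_px = NULL,
                             epsilon = 1e-3) {
  stopifnot(inherits(stack, "frame_stack"))
  if (normalize) stack <- normalize_brightness(stack, target = target)
  field <- NULL
  if (vignette) {
    field <- estimate_vignette(compute_average_frame(stack),
                               sigma_px = sigma_px, epsilon = epsilon)
    stack <- correct_vignette(stack, field)
  }
  list(subtracted = average_subtract(stack), vignette = field)
}
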