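#' Colormaps: encoding acquisition time as color
#'
#' A `trail_colormap` maps normalized time `u` in `[0, 1]` to an RGB triple by
#' piecewise-linear interpolation between ordered control points. Sequential
#' maps (blue -> red, cyan -> magenta) represent locomotory progression from
#' the start to the end of a window; diverging maps with a neutral midpoint
#' distinguish behavior before and after an intervention; `constant_white`
#' disables temporal encoding. Interpolation is performed in linear RGB: trail
#' pixels are formed by multiplying intensity by color, and linear RGB keeps
#' that product interpretable.
#'
#' @param points A data frame (or matrix) with columns `u`, `r`, `g`, `b`:
#'   `u` strictly increasing from 0 to 1, channels in `[0, 1]`.
#' @param name Identifier for the map.
#' @param kind One of `"sequential"`, `"diverging"`, `"custom"`.
#' @return A `trail_colormap`.
#' @examples
#' m <- colormap_from_points(data.frame(
#'   u = c(0, 0.5, 1),
#'   r = c(0, 1, 1), g = c(0, 1, 0), b = c(1, 1, 0)))
#' evaluate_colormap(m, c(0, 0.25, 1))
#' @export
colormap_from_points <- function(points, name = "custom", kind = "custom") {
  points <- as.data.frame(points)
  need <- c("u", "r", "g", "b")
  if (!all(need %in% names(points))) {
    if (ncol(points) == 4L) names(points) <- need
    else stop("`points` needs columns u, r, g, b", call. = FALSE)
  }
  points <- points[need]
  if (nrow(points) < 2L) {
    stop("a colormap needs at least 2 control points", call. = FALSE)
  }
  if (points$u[1L] != 0) {
    stop(sprintf("first control point must have u = 0 (got u = %g)",
                 points$u[1L]), call. = FALSE)
  }
  if (points$u[nrow(points)] != 1) {
    stop(sprintf("last control point must have u = 1 (got u = %g)",
                 points$u[nrow(points)]), call. = FALSE)
  }
  dup <- which(diff(points$u) <= 0)
  if (length(dup)) {
    stop(sprintf("control point u values must be strictly increasing (points %d and %d: u = %g, %g)",
                 dup[1L], dup[1L] + 1L, points$u[dup[1L]], points$u[dup[1L] + 1L]),
         call. = FALSE)
  }
  rgb <- as.matrix(points[c("r", "g", "b")])
  bad <- which(rgb < 0 | rgb > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("control point %d has channel value %g outside [0, 1]",
                 bad[1L, 1L], rgb[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  structure(list(name = name, u = points$u, rgb = unname(rgb),
                 kind = match.arg(kind, c("sequential", "diverging", "custom"))),
            class = "trail_colormap")
}

builtin_colormaps <- function() {
  pt <- function(u, r, g, b) data.frame(u = u, r = r, g = g, b = b)
  list(
    blue_red = colormap_from_points(
      pt(c(0, 1), c(0, 1), c(0, 0), c(1, 0)),
      name = "blue_red", kind = "sequential"),
    cyan_magenta = colormap_from_points(
      pt(c(0, 1), c(0, 1), c(1, 0), c(1, 1)),
      name = "cyan_magenta", kind = "sequential"),
    blue_white_red = colormap_from_points(
      pt(c(0, 0.5, 1), c(0, 1, 1), c(0, 1, 0), c(1, 1, 0)),
      name = "blue_white_red", kind = "diverging"),
    constant_white = colormap_from_points(
      pt(c(0, 1), c(1, 1), c(1, 1), c(1, 1)),
      name = "constant_white", kind = "sequential")
  )
}

#' Built-in colormaps
#'
#' Registry: `blue_red` (sequential; early times blue, late times red),
#' `cyan_magenta` (sequential), `blue_white_red` (diverging, white neutral
#' midpoint for pre/post-intervention encoding), `constant_white` (no
#' temporal encoding). Endpoint hues are pure primaries/secondaries.
#'
#' @param name Registry name.
#' @return A `trail_colormap`.
#' @export
trail_colormap <- function(name) {
  reg <- builtin_colormaps()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown colormap '%s'; available: %s",
                 name, paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[name]]
}

#' Evaluate a colormap at normalized times
#'
#' Piecewise-linear interpolation per channel between the bracketing control
#' points; exact at every control point.
#'
#' @param map A `trail_colormap`.
#' @param u Numeric vector of normalized times, each in `[0, 1]`.
#' @return `length(u) x 3` matrix of RGB values in `[0, 1]`.
#' @export
evaluate_colormap <- function(map, u) {
  stopifnot(inherits(map, "trail_colormap"))
  if (anyNA(u) || any(u < 0 | u > 1)) {
    stop("`u` must lie in [0, 1]; normalize time before evaluating",
         call. = FALSE)
  }
  out <- vapply(1:3, function(ch) {
    stats::approx(map$u, map$rgb[, ch], xout = u, rule = 2L)$y
  }, numeric(length(u)))
  matrix(out, nrow = length(u), ncol = 3L,
         dimnames = list(NULL, c("r", "g", "b")))
}

#' Reverse a colormap in time
#'
#' @param map A `trail_colormap`.
#' @return The map traversed from u = 1 to u = 0.
#' @export
reverse_colormap <- function(map) {
  stopifnot(inherits(map, "trail_colormap"))
  n <- length(map$u)
  colormap_from_points(
    data.frame(u = 1 - rev(map$u),
               r = rev(map$rgb[, 1L]),
               g = rev(map$rgb[, 2L]),
               b = rev(map$rgb[, 3L])),
    name = paste0(map$name, "_reversed"), kind = map$kind)
}

#' Read a user-defined colormap from a plain-text file
#'
#' Each non-comment row holds `u r g b`, whitespace-separated, values in
#' `[0, 1]`; `#` starts a comment.
#'
#' @param path Path to the text file.
#' @return A `trail_colormap`.
#' @export
read_colormap_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("colormap file '%s' not found", path), call. = FALSE)
  }
  tab <- utils::read.table(path, col.names = c("u", "r", "g", "b"),
                           comment.char = "#")
  colormap_from_points(tab, name = basename(path), kind = "custom")
}

# Resolve a colormap given as an object, registry name, or file path.
resolve_colormap <- function(x) {
  if (inherits(x, "trail_colormap")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% names(builtin_colormaps())) return(trail_colormap(x))
    if (file.exists(x)) return(read_colormap_file(x))
    stop(sprintf("colormap '%s' is neither a built-in (%s) nor a file", x,
                 paste(names(builtin_colormaps()), collapse = ", ")),
         call. = FALSE)
  }
  stop("`colormap` must be a trail_colormap, a built-in name, or a file path",
       call. = FALSE)
}

#' @export
print.trail_colormap <- function(x, ...) {
  cat(sprintf("<trail_colormap> '%s' (%s), %d control points\n",
              x$name, x$kind, length(x$u)))
  invisible(x)
}
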