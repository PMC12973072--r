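#' @importFrom stats median approx rnorm runif setNames
#' @importFrom utils write.csv read.csv
NULL

# ITU-R BT.601 luminance weights; the de-facto video standard.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

raster_ext <- function(path) tolower(tools::file_ext(path))

# Collapse a decoded raster (matrix or H x W x C array) to grayscale.
to_gray <- function(px, as_gray, what = "frame") {
  if (is.matrix(px)) return(px)
  nc <- dim(px)[3L]
  if (nc == 1L) return(px[, , 1L])
  if (!as_gray) {
    stop(sprintf("%s has %d channels; set as_gray = TRUE to reduce to luminance",
                 what, nc), call. = FALSE)
  }
  if (nc == 2L) return(px[, , 1L])            # gray + alpha
  px[, , 1L] * LUMA_WEIGHTS[1L] + px[, , 2L] * LUMA_WEIGHTS[2L] +
    px[, , 3L] * LUMA_WEIGHTS[3L]             # alpha (if any) ignored
}

read_raster <- function(path) {
  ext <- raster_ext(path)
  out <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path, all = TRUE, info = TRUE),
      stop(sprintf("unsupported raster format '.%s' (use PNG or TIFF)", ext),
           call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("cannot decode '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (!is.list(out)) out <- list(out)
  out
}

raster_bit_depth <- function(img, ext) {
  bps <- attr(img, "bits.per.sample")
  if (!is.null(bps) && bps %in% c(8L, 16L)) return(as.integer(bps))
  8L
}

#' Load a video into a frame stack
#'
#' Reads a lossless multi-page TIFF movie into the pipeline's normalized
#' grayscale representation. Intensities are rescaled from the source bit
#' depth to `[0, 1]` (an 8-bit value `v` maps to `v / 255`); color input is
#' reduced to BT.601 luminance when `as_gray` is set. TIFF containers carry
#' no frame-rate metadata, so `fps` must be supplied; frame times are
#' synthesized as `(i - 1) / fps`.
#'
#' Compressed video containers (AVI/MKV/MP4) are not decodable here; convert
#' such recordings to a multi-page TIFF or a numbered PNG sequence first
#' (a lossless route is recommended in any case, to prevent compression
#' artifacts from contaminating the average-subtracted frames).
#'
#' @param path Path to a multi-page TIFF (`.tif`/`.tiff`).
#' @param fps Frames per second of the recording (required).
#' @param as_gray Reduce color frames to luminance (default TRUE).
#' @return A [frame_stack].
#' @seealso [load_image_sequence()], [write_video()]
#' @export
load_video <- function(path, fps = NULL, as_gray = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  }
  ext <- raster_ext(path)
  if (ext %in% c("avi", "mkv", "mp4", "mov", "webm")) {
    stop(sprintf(paste0(
      "cannot decode '%s': compressed video containers are not supported; ",
      "convert the recording to a multi-page TIFF or a numbered PNG sequence"),
      path), call. = FALSE)
  }
  pages <- read_raster(path)
  if (length(pages) < 2L) {
    stop(sprintf(
      "'%s' holds %d frame(s); the pipeline needs at least 2 to average over",
      path, length(pages)), call. = FALSE)
  }
  if (is.null(fps)) {
    stop("frame rate unknown: TIFF stacks carry no fps metadata, supply `fps`",
         call. = FALSE)
  }
  depth <- raster_bit_depth(pages[[1L]], ext)
  mats <- lapply(seq_along(pages), function(i) {
    to_gray(pages[[i]], as_gray, what = sprintf("frame %d of '%s'", i, path))
  })
  stack_from_matrices(mats, fps = fps, source_bit_depth = depth)
}

stack_from_matrices <- function(mats, fps, source_bit_depth = 8L) {
  d <- dim(mats[[1L]])
  frames <- array(0, c(length(mats), d[1L], d[2L]))
  for (i in seq_along(mats)) frames[i, , ] <- mats[[i]]
  frame_stack(frames, fps = fps, source_bit_depth = source_bit_depth)
}

# Zero-pad every digit run so lexicographic order equals natural order
# (f2.png sorts before f10.png).
natural_key <- function(x) {
  m <- gregexpr("[0-9]+", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(runs) {
    if (length(runs)) formatC(sub("^0+(?=.)", "", runs, perl = TRUE),
                              width = 20L, flag = "0")
    else runs
  })
  x
}

#' Natural-order sort of file names
#'
#' Orders strings so that embedded integers compare numerically:
#' `f2.png` before `f10.png`.
#'
#' @param x Character vector of paths.
#' @return `x` in natural order.
#' @export
natural_sort <- function(x) {
  x[order(natural_key(basename(x)), x, method = "radix")]
}

#' Load a numbered image sequence into a frame stack
#'
#' Frames are ordered by natural sort of their file names and times are
#' synthesized as `(i - 1) / fps`. All frames must share shape and bit depth.
#'
#' @param pattern A glob (e.g. `"frames/f*.png"`) or a character vector of
#'   file paths.
#' @param fps Frames per second (required).
#' @param as_gray Reduce color frames to luminance (default TRUE).
#' @return A [frame_stack].
#' @export
load_image_sequence <- function(pattern, fps, as_gray = TRUE) {
  files <- if (length(pattern) == 1L && !file.exists(pattern[1L])) {
    Sys.glob(pattern)
  } else {
    pattern
  }
  if (length(files) < 2L) {
    stop(sprintf("need at least 2 frames; pattern matched %d file(s)",
                 length(files)), call. = FALSE)
  }
  if (missing(fps) || is.null(fps)) {
    stop("supply `fps`: image sequences carry no frame-rate metadata",
         call. = FALSE)
  }
  files <- natural_sort(files)
  depth <- NULL
  mats <- vector("list", length(files))
  for (i in seq_along(files)) {
    pages <- read_raster(files[i])
    if (length(pages) != 1L) {
      stop(sprintf("'%s' holds %d pages; sequence frames must be single images",
                   files[i], length(pages)), call. = FALSE)
    }
    m <- to_gray(pages[[1L]], as_gray, what = sprintf("'%s'", files[i]))
    if (i == 1L) {
      depth <- raster_bit_depth(pages[[1L]], raster_ext(files[i]))
    } else if (!identical(dim(m), dim(mats[[1L]]))) {
      stop(sprintf("frame shape mismatch: '%s' is %d x %d, expected %d x %d",
                   files[i], dim(m)[1L], dim(m)[2L],
                   dim(mats[[1L]])[1L], dim(mats[[1L]])[2L]), call. = FALSE)
    }
    mats[[i]] <- m
  }
  stack_from_matrices(mats, fps = fps, source_bit_depth = depth)
}

coerce_rgb_list <- function(frames) {
  if (inherits(frames, "frame_stack")) {
    frames <- lapply(seq_len(n_frames(frames)),
                     function(i) get_frame(frames, i))
  }
  if (is.array(frames) && length(dim(frames)) == 3L && dim(frames)[3L] == 3L) {
    frames <- list(frames)
  }
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a nonempty list of frames", call. = FALSE)
  }
  out <- lapply(frames, function(f) {
    if (is.matrix(f)) f <- gray_to_rgb(f)
    unclass(rgb_frame(f))
  })
  d <- dim(out[[1L]])
  for (i in seq_along(out)) {
    if (!identical(dim(out[[i]]), d)) {
      stop(sprintf("frame %d has shape %s; expected %s", i,
                   paste(dim(out[[i]]), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
    }
  }
  out
}

#' Write a video losslessly
#'
#' Writes an RGB (or grayscale) frame sequence as a multi-page TIFF with
#' deflate compression (lossless: a round-trip read reproduces every pixel
#' exactly at 8-bit quantization), or as a numbered PNG sequence when `path`
#' contains a `sprintf` frame-number template such as `%04d`. Lossy
#' containers are deliberately not provided: compression artifacts survive
#' average subtraction and pollute the trails.
#'
#' @param frames List of `(row, col, 3)` RGB arrays (grayscale matrices are
#'   promoted), or a [frame_stack].
#' @param path Output path: `.tif`/`.tiff` for a multi-page movie, or a PNG
#'   template like `out/frame_%04d.png`.
#' @param fps Nominal frame rate, recorded for validation only (TIFF stores
#'   no timing metadata; keep the value with the run's sidecar parameters).
#' @param lossless Must remain TRUE; FALSE errors, naming the lossless
#'   fallback, since no lossy codec is available.
#' @return Invisibly, the vector of files written.
#' @export
write_video <- function(frames, path, fps = NULL, lossless = TRUE) {
  frames <- coerce_rgb_list(frames)
  if (!is.null(fps) && (!is.numeric(fps) || fps <= 0)) {
    stop("`fps` must be a positive number", call. = FALSE)
  }
  if (!isTRUE(lossless)) {
    stop(paste0("no lossy codec is available; write lossless output ",
                "(multi-page TIFF or a PNG sequence template like '%04d.png')"),
         call. = FALSE)
  }
  ext <- raster_ext(path)
  qframes <- lapply(frames, quantize_8bit)
  if (grepl("%", basename(path), fixed = TRUE) && ext == "png") {
    files <- vapply(seq_along(qframes), function(i) sprintf(path, i),
                    character(1L))
    for (i in seq_along(qframes)) write_image(qframes[[i]], files[i])
    return(invisible(files))
  }
  if (!ext %in% c("tif", "tiff")) {
    stop(sprintf(paste0(
      "cannot write '%s': no codec for '.%s'; use a multi-page TIFF ",
      "(.tif) or a PNG image-sequence template (e.g. 'frame_%%04d.png')"),
      path, ext), call. = FALSE)
  }
  ok <- tryCatch(
    tiff::writeTIFF(qframes, path, bits.per.sample = 8L,
                    compression = "deflate"),
    error = function(e) {
      stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  invisible(path)
}

#' Read back an RGB trail video written by [write_video()]
#'
#' @param path Multi-page TIFF path, or PNG-sequence template/glob.
#' @return List of `(row, col, 3)` arrays in `[0, 1]`.
#' @export
read_rgb_video <- function(path) {
  files <- if (grepl("%", basename(path), fixed = TRUE)) {
    Sys.glob(gsub("%0?[0-9]*d", "*", path))
  } else {
    path
  }
  pages <- do.call(c, lapply(natural_sort(files), read_raster))
  lapply(pages, function(p) {
    if (is.matrix(p)) gray_to_rgb(p)
    else if (dim(p)[3L] >= 3L) p[, , 1:3, drop = FALSE]
    else gray_to_rgb(p[, , 1L])
  })
}

#' Write a single RGB frame as a PNG (or TIFF) still
#'
#' Round-trips exactly at 8-bit quantization.
#'
#' @param frame `(row, col, 3)` RGB array (grayscale matrix is promoted).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(frame, path) {
  if (is.matrix(frame)) frame <- gray_to_rgb(frame)
  frame <- quantize_8bit(unclass(rgb_frame(frame)))
  ext <- raster_ext(path)
  res <- tryCatch(
    switch(ext,
      png = png::writePNG(frame, path),
      tif = ,
      tiff = tiff::writeTIFF(frame, path, bits.per.sample = 8L,
                             compression = "deflate"),
      stop(sprintf("unsupported still format '.%s' (use PNG or TIFF)", ext),
           call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  invisible(path)
}

#' Check acquisition assumptions for continuous trails
#'
#' Trails stay continuous only when no worm travels more than one body length
#' between successive frames. This advisory check warns when the worst-case
#' inter-frame displacement (`max_speed_px_per_s` times the median frame
#' interval) exceeds `worm_length_px`; it never blocks processing.
#'
#' @param stack A [frame_stack].
#' @param worm_length_px Worm body length in pixels (> 0).
#' @param max_speed_px_per_s Fastest expected crawl speed in px/s (> 0).
#' @return Character vector of warnings (empty when assumptions hold).
#' @export
check_acquisition <- function(stack, worm_length_px, max_speed_px_per_s) {
  stopifnot(inherits(stack, "frame_stack"))
  if (worm_length_px <= 0 || max_speed_px_per_s <= 0) {
    stop("`worm_length_px` and `max_speed_px_per_s` must be positive",
         call. = FALSE)
  }
  out <- character(0)
  dt <- stats::median(diff(stack$times))
  disp <- max_speed_px_per_s * dt
  if (disp > worm_length_px) {
    out <- c(out, sprintf(paste0(
      "worst-case inter-frame displacement %.3g px exceeds one body length ",
      "(%.3g px) at the median frame interval %.3g s; trails may be ",
      "discontinuous -- acquire faster than %.3g fps"),
      disp, worm_length_px, dt, max_speed_px_per_s / worm_length_px))
  }
  out
}
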