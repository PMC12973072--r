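#' Synthetic locomotion scene description
#'
#' Describes a seedable simulation of worm-like locomotion on a plate-shaped
#' field, used to test every pipeline stage without external data. Worms are
#' rendered as isotropic Gaussian blobs (trail-level tests need no body
#' posture) following a two-state roam/dwell random walk; the field carries a
#' static radial-quadratic vignette and additive Gaussian sensor noise.
#' Defaults emulate a typical plate recording: 1200 x 1200 px at 1 frame per
#' second (about 100 um per pixel over a 9 cm plate), a single adult worm
#' roaming at ~2 px/s, imaged for 10 minutes. Tests and examples use smaller
#' fields and shorter durations; pass `shape` and `duration_s` explicitly.
#'
#' @param shape `(rows, cols)` in pixels.
#' @param fps Frames per second.
#' @param duration_s Recording length in seconds.
#' @param n_worms Number of worms (>= 0).
#' @param worm_sigma_px Gaussian blob standard deviation in pixels.
#' @param worm_peak Blob peak amplitude in `(0, 1]`.
#' @param polarity `"darkfield"` (bright worms on dark background) or
#'   `"brightfield"` (dark worms on bright background).
#' @param roam_speed_px_s,dwell_speed_px_s Crawl speed per state, px/s;
#'   dwell must not exceed roam.
#' @param switch_prob_per_s Per-second probability of switching state
#'   (symmetric two-state Markov chain), in `[0, 1]`.
#' @param turn_sigma_rad Per-frame heading change standard deviation in roam;
#'   dwelling turns 4x as sharply.
#' @param vignette_strength Radial-quadratic vignette depth in `[0, 1)`:
#'   field is `1 - strength * (r / r_max)^2` with `r_max` the half-diagonal.
#' @param noise_sigma Additive Gaussian noise standard deviation (>= 0).
#' @param background_level Static background intensity in `[0, 1]`.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return A `sim_scene` list.
#' @export
sim_scene <- function(shape = c(1200, 1200), fps = 1, duration_s = 600,
                      n_worms = 1L, worm_sigma_px = 2, worm_peak = 0.6,
                      polarity = c("darkfield", "brightfield"),
                      roam_speed_px_s = 2, dwell_speed_px_s = 0.3,
                      switch_prob_per_s = 0.05, turn_sigma_rad = 0.35,
                      vignette_strength = 0.2, noise_sigma = 0.01,
                      background_level = 0.1, seed = 1L) {
  polarity <- match.arg(polarity)
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(length(shape) == 2L && all(shape >= 4), "`shape` must be (rows, cols), each >= 4")
  chk(fps > 0, "`fps` must be positive")
  chk(duration_s > 0, "`duration_s` must be positive")
  chk(n_worms >= 0, "`n_worms` must be >= 0")
  chk(worm_sigma_px > 0, "`worm_sigma_px` must be positive")
  chk(worm_peak > 0 && worm_peak <= 1, "`worm_peak` must lie in (0, 1]")
  chk(dwell_speed_px_s >= 0 && roam_speed_px_s >= 0,
      "speeds must be nonnegative")
  chk(dwell_speed_px_s <= roam_speed_px_s,
      "`dwell_speed_px_s` must not exceed `roam_speed_px_s`")
  chk(switch_prob_per_s >= 0 && switch_prob_per_s <= 1,
      "`switch_prob_per_s` must lie in [0, 1]")
  chk(turn_sigma_rad >= 0, "`turn_sigma_rad` must be >= 0")
  chk(vignette_strength >= 0 && vignette_strength < 1,
      "`vignette_strength` must lie in [0, 1)")
  chk(noise_sigma >= 0, "`noise_sigma` must be >= 0")
  chk(background_level >= 0 && background_level <= 1,
      "`background_level` must lie in [0, 1]")
  structure(list(
    shape = as.integer(shape), fps = fps, duration_s = duration_s,
    n_worms = as.integer(n_worms), worm_sigma_px = worm_sigma_px,
    worm_peak = worm_peak, polarity = polarity,
    roam_speed_px_s = roam_speed_px_s, dwell_speed_px_s = dwell_speed_px_s,
    switch_prob_per_s = switch_prob_per_s, turn_sigma_rad = turn_sigma_rad,
    vignette_strength = vignette_strength, noise_sigma = noise_sigma,
    background_level = background_level, seed = as.integer(seed)),
    class = "sim_scene")
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf(
    "<sim_scene> %d x %d px, %g fps, %g s, %d worm(s), %s, seed %d\n",
    x$shape[1L], x$shape[2L], x$fps, x$duration_s, x$n_worms, x$polarity,
    x$seed))
  invisible(x)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

reflect_into <- function(p, lo, hi) {
  # fold a coordinate back into [lo, hi] by mirror reflection
  span <- hi - lo
  for (pass in 1:100) {
    below <- p < lo
    above <- p > hi
    if (!any(below | above)) break
    p[below] <- 2 * lo - p[below]
    p[above] <- 2 * hi - p[above]
  }
  pmin(pmax(p, lo), hi)
}

# Two-state roam/dwell random walk; consumes the RNG stream first so
# sim_trajectories(scene) reproduces exactly the truth that simulate_scene()
# embeds in its rendered frames.
traj_impl <- function(scene) {
  nt <- max(2L, as.integer(round(scene$duration_s * scene$fps)))
  dt <- 1 / scene$fps
  nw <- scene$n_worms
  if (nw == 0L) {
    return(tibble::tibble(frame = integer(0), worm_id = integer(0),
                          row = numeric(0), col = numeric(0),
                          state = character(0)))
  }
  nr <- scene$shape[1L]; nc <- scene$shape[2L]
  p_frame <- 1 - (1 - scene$switch_prob_per_s)^dt
  speeds <- c(roam = scene$roam_speed_px_s, dwell = scene$dwell_speed_px_s)

  # start positions uniform in a central disk (the plate), headings uniform
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rad <- 0.4 * min(nr, nc)
  th0 <- runif(nw, 0, 2 * pi)
  rr0 <- rad * sqrt(runif(nw))
  row <- cr + rr0 * sin(th0)
  col <- cc + rr0 * cos(th0)
  heading <- runif(nw, 0, 2 * pi)
  state <- ifelse(runif(nw) < 0.5, 1L, 2L)   # 1 roam, 2 dwell

  rows <- matrix(0, nt, nw); cols <- matrix(0, nt, nw)
  states <- matrix(0L, nt, nw)
  rows[1L, ] <- row; cols[1L, ] <- col; states[1L, ] <- state
  for (t in 2:nt) {
    flip <- runif(nw) < p_frame
    state <- ifelse(flip, 3L - state, state)
    turn_sd <- scene$turn_sigma_rad * ifelse(state == 2L, 4, 1)
    heading <- heading + rnorm(nw, 0, turn_sd)
    step <- speeds[state] * dt
    row <- reflect_into(row + step * sin(heading), 1, nr)
    col <- reflect_into(col + step * cos(heading), 1, nc)
    rows[t, ] <- row; cols[t, ] <- col; states[t, ] <- state
  }
  out <- tibble::tibble(
    frame = rep(seq_len(nt), times = nw),
    worm_id = rep(seq_len(nw), each = nt),
    row = as.vector(rows), col = as.vector(cols),
    state = c("roam", "dwell")[as.vector(states)])
  out[order(out$frame, out$worm_id), ]
}

render_impl <- function(scene, truth) {
  nr <- scene$shape[1L]; nc <- scene$shape[2L]
  nt <- max(2L, as.integer(round(scene$duration_s * scene$fps)))
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r_max <- sqrt((nr - cr)^2 + (nc - cc)^2)
  vfield <- if (scene$vignette_strength > 0) {
    rr <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+")
    1 - scene$vignette_strength * rr / r_max^2
  } else NULL

  sgn <- if (scene$polarity == "darkfield") 1 else -1
  sig <- scene$worm_sigma_px
  halo <- ceiling(4 * sig)
  frames <- array(0, c(nt, nr, nc))
  by_frame <- split(truth[c("row", "col")], truth$frame)
  for (t in seq_len(nt)) {
    img <- matrix(scene$background_level, nr, nc)
    tf <- by_frame[[as.character(t)]]
    if (!is.null(tf) && nrow(tf)) {
      for (k in seq_len(nrow(tf))) {
        wr <- tf$row[k]; wc <- tf$col[k]
        i0 <- max(1L, floor(wr - halo)); i1 <- min(nr, ceiling(wr + halo))
        j0 <- max(1L, floor(wc - halo)); j1 <- min(nc, ceiling(wc + halo))
        blob <- scene$worm_peak * exp(-outer((i0:i1 - wr)^2,
                                             (j0:j1 - wc)^2, "+") /
                                        (2 * sig^2))
        img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + sgn * blob
      }
    }
    if (!is.null(vfield)) img <- img * vfield
    if (scene$noise_sigma > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, scene$noise_sigma), nr, nc)
    }
    frames[t, , ] <- clip01(img)
  }
  frame_stack(frames, fps = scene$fps)
}

#' Simulate a locomotion recording with ground truth
#'
#' Runs the two-state roam/dwell walk for every worm (per-second switch
#' probability converted to per-frame as `1 - (1 - p)^dt`; heading a wrapped
#' Gaussian random walk, 4x broader while dwelling; step length
#' `speed / fps`; mirror reflection at the field edges) and renders each
#' frame: static background, plus/minus Gaussian worm blobs, multiplied by
#' the radial vignette, plus sensor noise, clipped to `[0, 1]`. The same
#' seed gives bit-identical frames and truth.
#'
#' @param scene A [sim_scene].
#' @return List with `stack` (a [frame_stack]) and `truth` (a tibble with
#'   columns `frame`, `worm_id`, `row`, `col`, `state`, and attributes
#'   `shape` and `fps`).
#' @export
simulate_scene <- function(scene) {
  stopifnot(inherits(scene, "sim_scene"))
  with_seed(scene$seed, {
    truth <- traj_impl(scene)
    stack <- render_impl(scene, truth)
    attr(truth, "shape") <- scene$shape
    attr(truth, "fps") <- scene$fps
    list(stack = stack, truth = truth)
  })
}

#' Ground-truth trajectories only (no rendering)
#'
#' Identical to the truth returned by [simulate_scene()] for the same scene
#' (the trajectory random-walk consumes the seed's stream first), useful for
#' long-run statistical checks where rendering frames would be wasteful.
#'
#' @param scene A [sim_scene].
#' @return The ground-truth tibble.
#' @export
sim_trajectories <- function(scene) {
  stopifnot(inherits(scene, "sim_scene"))
  out <- with_seed(scene$seed, traj_impl(scene))
  attr(out, "shape") <- scene$shape
  attr(out, "fps") <- scene$fps
  out
}

#' Ideal trail mask from ground truth
#'
#' Union of disks of `radius_px` around every ground-truth centroid in the
#' given frames: the oracle that trail-coverage tests compare rendered trail
#' frames against.
#'
#' @param truth Ground-truth tibble from [simulate_scene()].
#' @param frames Integer vector of frame numbers to include.
#' @param radius_px Disk radius in pixels.
#' @param shape Field shape; default taken from the truth's attribute.
#' @return Logical `(rows, cols)` matrix.
#' @export
ideal_trail_mask <- function(truth, frames, radius_px,
                             shape = attr(truth, "shape")) {
  if (is.null(shape)) stop("supply `shape`", call. = FALSE)
  mask <- matrix(FALSE, shape[1L], shape[2L])
  sel <- truth[truth$frame %in% frames, , drop = FALSE]
  if (!nrow(sel)) return(mask)
  r <- ceiling(radius_px)
  for (k in seq_len(nrow(sel))) {
    wr <- sel$row[k]; wc <- sel$col[k]
    i0 <- max(1L, floor(wr - r)); i1 <- min(shape[1L], ceiling(wr + r))
    j0 <- max(1L, floor(wc - r)); j1 <- min(shape[2L], ceiling(wc + r))
    d2 <- outer((i0:i1 - wr)^2, (j0:j1 - wc)^2, "+")
    mask[i0:i1, j0:j1] <- mask[i0:i1, j0:j1] | d2 <= radius_px^2
  }
  mask
}

#' Write ground truth as CSV
#'
#' Columns: `frame`, `worm_id`, `row`, `col`, `state`.
#'
#' @param truth Ground-truth tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth)[c("frame", "worm_id", "row", "col",
                                          "state")],
                   path, row.names = FALSE)
  invisible(path)
}
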