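# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write into tempdir().

make_stack <- function(mats, fps = 1) {
  frames <- array(0, c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) frames[i, , ] <- mats[[i]]
  frame_stack(frames, fps = fps)
}

rand_stack <- function(nt, nr, nc, fps = 1, seed = 1) {
  set.seed(seed)
  frame_stack(array(runif(nt * nr * nc), c(nt, nr, nc)), fps = fps)
}

# A deterministic "worm" lighting one distinct pixel per frame along a path;
# everything else stays at `bg`. Returns the raw stack plus the visited
# (row, col) per frame.
dot_walk_stack <- function(n, nr = 16, nc = 16, bg = 0, lit = 1, fps = 1) {
  stopifnot(n <= nr * nc)
  rows <- ((seq_len(n) - 1) %% nr) + 1
  cols <- ((seq_len(n) - 1) %/% nr) + 1
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(bg, nr, nc)
    m[rows[i], cols[i]] <- lit
    m
  })
  list(stack = make_stack(mats, fps = fps), rows = rows, cols = cols)
}

# Independent oracle for the windowed projection: brute-force per-pixel
# scan, late-to-early so the first maximum found is the latest tied frame.
bf_project <- function(stack, idx, gain, offset, fade_fraction, map) {
  n <- length(idx)
  u <- if (n == 1) 1 else (seq_len(n) - 1) / (n - 1)
  m <- round(fade_fraction * n)
  w <- if (m < 1) rep(1, n) else ifelse(seq_len(n) - 1 < m,
                                        (seq_len(n) - 1) / m, 1)
  shp <- frame_shape(stack)
  out <- array(0, c(shp, 3))
  for (r in seq_len(shp[1])) {
    for (cc in seq_len(shp[2])) {
      best <- 0; kwin <- 0
      for (k in n:1) {   # late to early: first hit wins ties
        v <- min(1, max(0, gain * stack$frames[idx[k], r, cc] - offset)) * w[k]
        if (v > best) { best <- v; kwin <- k }
      }
      if (kwin > 0) {
        enh <- min(1, max(0, gain * stack$frames[idx[kwin], r, cc] - offset))
        out[r, cc, ] <- enh * w[kwin] * evaluate_colormap(map, u[kwin])[1, ]
      }
    }
  }
  out
}

radial_vignette <- function(nr, nc, strength) {
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rmax2 <- (nr - cr)^2 + (nc - cc)^2
  1 - strength * outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+") / rmax2
}

interior_cv <- function(m, border_frac = 0.05) {
  b <- ceiling(border_frac * min(dim(m)))
  inner <- m[(b + 1):(nrow(m) - b), (b + 1):(ncol(m) - b)]
  stats::sd(inner) / mean(inner)
}
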