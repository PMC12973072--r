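test_that("contrast gain and noise-floor offset follow max(0, gain*v - offset)", {
  m <- matrix(c(0, 0.05, 0.3, 1), 2, 2)
  expect_equal(enhance(m, 1, 0), m)                      # identity
  expect_equal(enhance(matrix(0.05), 2, 0.2), matrix(0)) # below floor
  expect_equal(enhance(matrix(0.3), 2, 0.2), matrix(0.4))
  expect_equal(enhance(matrix(0.9), 2, 0.2), matrix(1))  # clipped above
  expect_error(enhance(m, 0, 0), "gain")
  expect_error(enhance(m, 1, 1), "offset")
})

test_that("fade weights ramp only over the oldest frames", {
  expect_equal(fade_weight(0:9, 10, 0), rep(1, 10))
  expect_equal(fade_weight(0:9, 10, 0.3),
               c(0, 1 / 3, 2 / 3, rep(1, 7)))
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    f <- runif(1, 0, 0.5)
    w <- fade_weight(0:(n - 1), n, f)
    expect_equal(w[n], 1)               # newest frame never faded
    expect_true(all(diff(w) >= 0))      # nondecreasing toward the present
    expect_true(all(w >= 0 & w <= 1))
    m <- round(f * n)
    if (m >= 1) expect_equal(w[1], 0)   # oldest frame invisible
  }
  expect_error(fade_weight(10, 10, 0.2), "out of range")
  expect_error(fade_weight(0, 10, 0.7), "0.5")
})

test_that("colorize multiplies intensity, time color and weight", {
  m <- matrix(c(1, 0.5, 0, 0.25), 2, 2)
  expect_true(all(colorize(m, 0.3, trail_colormap("blue_red"), 0) == 0))
  px <- colorize(matrix(1), 0, trail_colormap("blue_red"), 1)
  expect_equal(as.vector(px), c(0, 0, 1))    # earliest time renders blue
  gr <- colorize(matrix(0.5), 0.7, trail_colormap("constant_white"), 1)
  expect_equal(as.vector(gr), c(0.5, 0.5, 0.5))
  expect_error(colorize(m, 0.5, trail_colormap("blue_red"), 2), "weight")
})

test_that("windowed projection matches the brute-force per-pixel oracle bit-exactly", {
  p <- trail_params(window_s = "full", fade_fraction = 0,
                    gain = 1, offset = 0, colormap = "constant_white")
  set.seed(52)
  for (rep in 1:20) {
    st <- frame_stack(array(runif(16 * 16 * 8), c(8, 16, 16)), fps = 1)
    got <- project_window(st, 1:8, p)$image
    ref <- bf_project(st, 1:8, 1, 0, 0, trail_colormap("constant_white"))
    expect_identical(got, ref)
    # and with gain/offset/fade/color engaged
    p2 <- trail_params(window_s = "full", fade_fraction = 0.25, gain = 3,
                       offset = 0.3, colormap = "blue_red")
    got2 <- project_window(st, 2:7, p2)$image
    ref2 <- bf_project(st, 2:7, 3, 0.3, 0.25, trail_colormap("blue_red"))
    expect_equal(got2, ref2, tolerance = 1e-14)
  }
})

test_that("projection is associative over window partitions (fade 0, white map)", {
  p <- trail_params(window_s = "full", fade_fraction = 0, gain = 2,
                    offset = 0.1, colormap = "constant_white")
  set.seed(53)
  for (rep in 1:5) {
    st <- frame_stack(array(runif(12 * 9 * 9), c(12, 9, 9)), fps = 1)
    whole <- project_window(st, 1:12, p)$image
    for (cut in c(3, 6, 10)) {
      a <- project_window(st, 1:cut, p)$image
      b <- project_window(st, (cut + 1):12, p)$image
      expect_identical(pmax(a, b), whole)
    }
  }
})

test_that("equal-intensity ties resolve to the later frame", {
  mats <- rep(list(matrix(0, 5, 5)), 4)
  mats[[2]][3, 3] <- 0.8
  mats[[4]][3, 3] <- 0.8   # same pixel, same intensity, later
  st <- make_stack(mats)
  p <- trail_params(window_s = "full", fade_fraction = 0, gain = 1,
                    offset = 0, colormap = "blue_red")
  tf <- project_window(st, 1:4, p)
  expect_equal(tf$image[3, 3, ],
               0.8 * evaluate_colormap(trail_colormap("blue_red"), 1)[1, ],
               ignore_attr = TRUE)
  # oracle agrees: bf_project scans late-to-early
  expect_equal(tf$image, bf_project(st, 1:4, 1, 0, 0,
                                    trail_colormap("blue_red")))
})

test_that("a single-pixel walker renders each visit at exactly its time color", {
  dw <- dot_walk_stack(9, nr = 6, nc = 6)
  sub <- average_subtract(dw$stack)
  p <- trail_params(window_s = "full", fade_fraction = 0, gain = 1,
                    offset = 0, colormap = "blue_red")
  tf <- render_still(sub, p)
  enh <- 1 - 1 / 9    # |1 - mean| at the lit frame
  for (i in 1:9) {
    u <- (i - 1) / 8
    expect_equal(tf$image[dw$rows[i], dw$cols[i], ],
                 enh * evaluate_colormap(trail_colormap("blue_red"), u)[1, ],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # never-visited pixels carry only the small 1/9 residue, tinted by their
  # own argmax frame; with offset above that residue they go exactly black
  p2 <- trail_params(window_s = "full", fade_fraction = 0, gain = 1,
                     offset = 0.2, colormap = "blue_red")
  tf2 <- render_still(sub, p2)
  visited <- cbind(dw$rows, dw$cols)
  blacks <- tf2$image
  for (i in 1:9) blacks[dw$rows[i], dw$cols[i], ] <- 0
  expect_true(all(blacks == 0))
})

test_that("stills are symmetric under time reversal with a reversed map", {
  set.seed(54)
  st <- frame_stack(array(runif(7 * 8 * 8), c(7, 8, 8)), fps = 1)
  sub <- average_subtract(st)
  rev_sub <- set_frames(sub, sub$frames[7:1, , ])
  # gain kept below the clipping point: clipping would manufacture ties,
  # which reverse asymmetrically by design
  fwd <- render_still(sub, trail_params(window_s = "full", fade_fraction = 0,
                                        gain = 1.2, offset = 0.05,
                                        colormap = "blue_red"))
  bwd <- render_still(rev_sub,
                      trail_params(window_s = "full", fade_fraction = 0,
                                   gain = 1.2, offset = 0.05,
                                   colormap = reverse_colormap(
                                     trail_colormap("blue_red"))))
  # ties (identical values at the same pixel in two frames) are the only
  # asymmetry; continuous random intensities have none
  expect_equal(fwd$image, bwd$image, tolerance = 1e-12)
})

test_that("static scenes and all-zero windows render black", {
  static <- average_subtract(make_stack(rep(list(matrix(0.3, 6, 6)), 8)))
  tf <- render_still(static)
  expect_true(all(tf$image == 0))
  expect_error(project_window(static, integer(0), trail_params()), "empty")
  expect_error(project_window(static, c(1L, 3L), trail_params()),
               "contiguous")
  expect_error(project_window(static, 7:9, trail_params()), "outside")
})

test_that("video mode uses trailing windows of round(window_s * fps) frames", {
  dw <- dot_walk_stack(80, nr = 10, nc = 10)
  sub <- average_subtract(dw$stack)
  p <- trail_params(window_s = 60, fade_fraction = 0, gain = 1, offset = 0)
  tfs <- render_video(sub, p)
  expect_length(tfs, 80)
  # truncated startup, then exactly 60 frames (59 s span at 1 fps)
  expect_equal(tfs[[1]]$window, c(0, 0))
  expect_equal(tfs[[30]]$window, c(0, 29))
  expect_equal(tfs[[60]]$window, c(0, 59))
  expect_equal(tfs[[61]]$window, c(1, 60))
  expect_equal(tfs[[80]]$window, c(20, 79))

  p20 <- trail_params(window_s = 20, fade_fraction = 0, gain = 1, offset = 0)
  tfs20 <- render_video(sub, p20)
  expect_equal(tfs20[[80]]$window, c(60, 79))   # 20 frames per window

  # a window longer than the recording falls back to one full projection
  short <- average_subtract(dot_walk_stack(10, nr = 6, nc = 6)$stack)
  expect_warning(out <- render_video(short, p20), "single")
  expect_length(out, 1)
  expect_equal(out[[1]]$window, c(0, 9))
})

test_that("non-overlapping windows recompose to the full still (max algebra)", {
  n <- 10
  dw <- dot_walk_stack(2 * n + 1, nr = 8, nc = 8)
  sub <- average_subtract(dw$stack)
  p <- trail_params(window_s = n, fade_fraction = 0, gain = 1, offset = 0,
                    colormap = "constant_white", stride = n)
  tfs <- render_video(sub, p)
  acc <- tfs[[1]]$image
  for (k in seq_along(tfs)[-1]) acc <- pmax(acc, tfs[[k]]$image)
  still <- render_still(sub, trail_params(window_s = "full",
                                          fade_fraction = 0, gain = 1,
                                          offset = 0,
                                          colormap = "constant_white"))
  expect_identical(acc, still$image)
})

test_that("raising the offset never lights a black pixel", {
  set.seed(55)
  st <- average_subtract(frame_stack(array(runif(6 * 10 * 10),
                                           c(6, 10, 10)), fps = 1))
  lit_at <- function(off) {
    img <- render_still(st, trail_params(window_s = "full", gain = 2,
                                         offset = off,
                                         fade_fraction = 0))$image
    apply(img, c(1, 2), max) > 0
  }
  lo <- lit_at(0.05); mid <- lit_at(0.3); hi <- lit_at(0.6)
  expect_true(all(mid <= lo))
  expect_true(all(hi <= mid))
})

test_that("the newest lit frame dominates the worm's current position", {
  # walker revisits: position pattern 1,2,3,2,1 over 5 frames
  mats <- rep(list(matrix(0, 5, 5)), 5)
  pos <- list(c(2, 2), c(3, 3), c(4, 4), c(3, 3), c(2, 2))
  for (i in 1:5) mats[[i]][pos[[i]][1], pos[[i]][2]] <- 1
  sub <- average_subtract(make_stack(mats))
  p <- trail_params(window_s = "full", fade_fraction = 0, gain = 1,
                    offset = 0, colormap = "blue_red")
  tf <- render_still(sub, p)
  # pixel (2,2): visited at frames 1 and 5 with equal intensity -> u = 1 (red)
  px <- tf$image[2, 2, ]
  expect_gt(px[1], 0); expect_equal(px[3], 0)
  # pixel (3,3): frames 2 and 4 -> u of frame 4 = 3/4 (red-dominant)
  px2 <- tf$image[3, 3, ]
  expect_gt(px2[1], px2[3])
})
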