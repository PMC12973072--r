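test_that("brightness normalization equalizes per-frame means", {
  st <- make_stack(list(matrix(0.2, 4, 4), matrix(0.4, 4, 4)))
  out <- normalize_brightness(st, target = "auto")  # grand mean 0.3
  expect_equal(out$frames, array(0.3, c(2, 4, 4)))

  st2 <- rand_stack(6, 8, 8, seed = 5)
  out2 <- normalize_brightness(st2, target = 0.3)
  expect_true(all(abs(apply(out2$frames, 1, mean) - 0.3) < 1e-6))

  # a stack already at target is unchanged
  expect_equal(normalize_brightness(out2, target = 0.3)$frames, out2$frames,
               tolerance = 1e-12)

  st3 <- make_stack(list(matrix(0.5, 3, 3), matrix(0, 3, 3)))
  expect_error(normalize_brightness(st3), "frame 2")
})

test_that("average frame is the brute-force per-pixel temporal mean", {
  st <- rand_stack(4, 3, 3, seed = 9)
  avg <- compute_average_frame(st)
  ref <- matrix(0, 3, 3)
  for (r in 1:3) for (cc in 1:3) ref[r, cc] <- mean(st$frames[, r, cc])
  expect_equal(avg$pixels, ref)
  expect_identical(avg$n_frames, 4L)

  same <- make_stack(rep(list(matrix(0.37, 3, 3)), 5))
  expect_equal(compute_average_frame(same)$pixels, matrix(0.37, 3, 3))
  half <- make_stack(list(matrix(0, 3, 3), matrix(1, 3, 3)))
  expect_equal(compute_average_frame(half)$pixels, matrix(0.5, 3, 3))
  one <- frame_stack(array(0.5, c(1, 3, 3)), fps = 1)
  expect_error(compute_average_frame(one), "at least 2")
})

test_that("gaussian blur matches a direct convolution oracle and preserves constants", {
  set.seed(21)
  m <- matrix(runif(11 * 9), 11, 9)
  sig <- 1.3
  r <- ceiling(4 * sig)
  w <- dnorm(-r:r, sd = sig); w <- w / sum(w)
  ext <- function(v, p) {            # antisymmetric edge extension
    n <- length(v)
    if (p < 1) 2 * v[1] - v[2 - p] else if (p > n) 2 * v[n] - v[2 * n - p]
    else v[p]
  }
  conv1 <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(w * vapply(i + (-r:r), function(p) ext(v, p), numeric(1)))
    }, numeric(1))
  }
  ref <- apply(apply(m, 2, conv1), 1, conv1)  # rows then cols; result transposed
  expect_equal(gaussian_blur(m, sig), t(ref), tolerance = 1e-12)
  expect_equal(gaussian_blur(matrix(0.4, 7, 7), 2), matrix(0.4, 7, 7),
               tolerance = 1e-12)
  expect_error(gaussian_blur(m, 0), "positive")
})

test_that("vignette field has spatial mean 1, floor epsilon, and localizes peaks", {
  uni <- compute_average_frame(make_stack(rep(list(matrix(0.6, 9, 9)), 3)))
  f1 <- estimate_vignette(uni, sigma_px = 2)
  expect_equal(f1$field, matrix(1, 9, 9), tolerance = 1e-12)

  st <- rand_stack(4, 12, 10, seed = 2)
  f2 <- estimate_vignette(compute_average_frame(st), sigma_px = 1.5,
                          epsilon = 1e-3)
  expect_equal(mean(f2$field), 1, tolerance = 1e-12)
  expect_gte(min(f2$field), 1e-3)

  # with the mirror boundary, blur at sigma far beyond the frame approaches
  # the global mean, so the normalized field approaches uniform 1
  f3 <- estimate_vignette(compute_average_frame(st), sigma_px = 500,
                          boundary = "reflect")
  expect_lt(max(abs(f3$field - 1)), 0.02)
  # the slope-preserving default instead reproduces linear illumination
  # ramps exactly, at any sigma
  ramp <- outer(seq(0.2, 0.8, length.out = 12), rep(1, 10))
  expect_equal(gaussian_blur(ramp, 4), ramp, tolerance = 1e-12)
  expect_equal(gaussian_blur(t(ramp), 30), t(ramp), tolerance = 1e-12)

  # isolated bright pixel, small sigma: field peaks there, mean exactly 1
  spot <- matrix(0.1, 15, 15); spot[5, 11] <- 1
  f4 <- estimate_vignette(
    compute_average_frame(make_stack(list(spot, spot))), sigma_px = 1)
  expect_equal(which(f4$field == max(f4$field), arr.ind = TRUE)[1, ],
               c(row = 5, col = 11))
  expect_equal(mean(f4$field), 1, tolerance = 1e-12)

  expect_error(estimate_vignette(uni, sigma_px = -1), "sigma")
  expect_error(estimate_vignette(uni, epsilon = 0), "epsilon")
})

test_that("vignette correction flattens a vignette-degraded flat scene >= 10x", {
  nr <- 100
  V <- radial_vignette(nr, nr, 0.4)
  st <- make_stack(rep(list(0.8 * V), 4))
  fld <- estimate_vignette(compute_average_frame(st), sigma_px = nr / 8)
  cor <- correct_vignette(st, fld)
  cv_raw <- interior_cv(get_frame(st, 1))
  cv_cor <- interior_cv(get_frame(cor, 1))
  expect_lt(cv_cor, 0.01)           # spatially flat away from borders
  expect_gte(cv_raw / cv_cor, 10)
})

test_that("vignette correction identity, clipping and shape contracts", {
  st <- rand_stack(3, 6, 6, seed = 4)
  ones <- structure(list(field = matrix(1, 6, 6), sigma_px = 1,
                         epsilon = 1e-3), class = "vignette_field")
  expect_equal(correct_vignette(st, ones)$frames, st$frames)

  dark <- ones; dark$field[2, 2] <- 1e-3   # division would exceed 1: clipped
  out <- correct_vignette(st, dark)
  expect_equal(out$frames[, 2, 2], rep(1, 3))
  expect_lte(max(out$frames), 1)

  small <- ones; small$field <- matrix(1, 5, 6)
  expect_error(correct_vignette(st, small), "5x6")
})

test_that("average subtraction isolates change and is polarity-symmetric", {
  static <- make_stack(rep(list(matrix(0.42, 5, 5)), 10))
  expect_true(all(average_subtract(static)$frames == 0))

  # single bright pixel in 1 of 10 frames: |1 - 0.1| there, 0.1 elsewhere
  mats <- rep(list(matrix(0, 6, 6)), 10)
  mats[[3]][4, 4] <- 1
  sub <- average_subtract(make_stack(mats))
  expect_equal(sub$frames[3, 4, 4], 0.9)
  expect_equal(sub$frames[7, 4, 4], 0.1)
  expect_true(all(sub$frames[, 1, 1] == 0))

  # inverting the stack leaves the output unchanged (bright/dark symmetry)
  st <- rand_stack(8, 7, 7, seed = 6)
  inv <- set_frames(st, 1 - st$frames)
  expect_lt(max(abs(average_subtract(st)$frames -
                      average_subtract(inv)$frames)), 1e-12)

  expect_error(average_subtract(frame_stack(array(0.1, c(1, 3, 3)), fps = 1)),
               "at least 2")
})

test_that("preprocess_stack chains the stages and keeps static scenes at zero", {
  V <- radial_vignette(40, 40, 0.3)
  st <- make_stack(rep(list(0.7 * V), 6))
  out <- preprocess_stack(st)   # normalize + vignette + subtract
  expect_true(all(out$subtracted$frames == 0))
  expect_s3_class(out$vignette, "vignette_field")
  out2 <- preprocess_stack(st, vignette = FALSE)
  expect_null(out2$vignette)
})
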