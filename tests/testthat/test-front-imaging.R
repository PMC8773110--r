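test_that("binarize applies the up-to-and-including margin threshold", {
  rule <- binarization_rule(margin = 90)
  expect_equal(sum(binarize(uniform_frame(c(200, 200, 200)), rule)), 0)
  # boundary semantics: grayscale exactly 90 counts as corroded
  expect_equal(sum(binarize(uniform_frame(c(90, 90, 90)), rule)), 64)
  expect_equal(sum(binarize(uniform_frame(c(91, 91, 91)), rule)), 0)
})

test_that("binarize rejects non-8-bit input with an explicit message", {
  f <- array(runif(48), dim = c(4, 4, 3))          # 0-1 floats
  expect_error(binarize(f), "8-bit")
  expect_error(binarize(array(0L, c(4, 4, 2))), "RGB")
  f2 <- uniform_frame(c(10, 10, 10)); f2[1, 1, 1] <- 300L
  expect_error(binarize(f2), "8-bit")
})

test_that("mask-1 count equals the rasterized corroded annulus exactly", {
  scene <- test_scene(r0 = 80, n_frames = 2)
  s <- 17.3
  img <- render_frame(scene, s = s, add_noise = FALSE)
  mask <- binarize(img)
  # independent rasterization of the same geometry
  dist <- corrfront:::scene_dist(scene)
  annulus <- sum(dist <= scene$corroded_outer_px & dist > (80 - s))
  expect_equal(sum(mask), annulus)
})

test_that("binarize is idempotent under recoloring corroded pixels", {
  scene <- test_scene(r0 = 60, n_frames = 2, noise_sd = 5)
  img <- corrfront:::with_seed(3, render_frame(scene, s = 10))
  mask <- binarize(img)
  img2 <- img
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[mask == 1L] <- scene$corroded_color[ch]
    img2[, , ch] <- plane
  }
  expect_identical(binarize(img2), mask)
})

test_that("estimate_radius implements the pixel-count formula", {
  N <- 30
  expect_equal(estimate_radius(matrix(0L, N, N)), sqrt(N^2 / pi))
  expect_equal(estimate_radius(matrix(1L, N, N)), 0)  # fully corroded
  expect_error(estimate_radius(matrix(0L, 0, 0)), "empty")
})

test_that("estimate_radius is monotone: adding corroded pixels never grows r", {
  set.seed(5)
  mask <- matrix(0L, 40, 40)
  r_prev <- estimate_radius(mask)
  for (i in 1:25) {
    idx <- sample(which(mask == 0L), 20)
    mask[idx] <- 1L
    r_new <- estimate_radius(mask)
    expect_lte(r_new, r_prev)
    r_prev <- r_new
  }
})

test_that("a rendered disk is recovered at its drawn radius", {
  scene <- test_scene(r0 = 100, n_frames = 2)
  img <- render_frame(scene, s = 0, add_noise = FALSE)
  r <- estimate_radius(binarize(img), test_roi(scene))
  expect_lt(abs(r - 100), 1)
})

test_that("extract_front_trace recovers s(t) and the sqrt-t exponent", {
  scene <- test_scene(r0 = 100, n_frames = 40)
  tr <- simulate_front_trace(sqrt_law(alpha = 1), duration = 195, step = 5)
  fs <- render_frames(tr, scene)
  rec <- extract_front_trace(fs, roi = test_roi(scene))
  expect_lt(max(abs(rec$s - tr$s)), 1)            # end-to-end <= 1 px
  keep <- rec$t > 0
  slope <- coef(lm(log(rec$s[keep]) ~ log(rec$t[keep])))[2]
  expect_lt(abs(slope - 0.5), 0.01)
})

test_that("degenerate series are rejected", {
  scene <- test_scene(n_frames = 3)
  img <- render_frame(scene, 0, add_noise = FALSE)
  tr <- extract_front_trace(list(img, img, img), times = c(0, 5, 10))
  expect_true(all(tr$s == 0))                     # identical frames
  expect_error(extract_front_trace(list(img), times = 0), ">= 2 frames")
  expect_error(extract_front_trace(list(img, img), times = NULL),
               "timestamps")
  img_small <- render_frame(test_scene(r0 = 50, size = 128), 0,
                            add_noise = FALSE)
  expect_error(extract_front_trace(list(img, img_small), times = c(0, 5)),
               "dimensions")
})

test_that("frames survive a PNG round trip and a multipage TIFF round trip", {
  scene <- test_scene(r0 = 40, size = 96, n_frames = 3, noise_sd = 5)
  tr <- simulate_front_trace(sqrt_law(), duration = 10, step = 5)
  fs <- render_frames(tr, scene)
  d <- withr::local_tempdir()
  paths <- write_frames(fs, d, format = "png")
  expect_identical(read_frames(paths), fs$frames)
  tpath <- write_frames(fs, d, format = "tiff")
  expect_identical(read_frames(tpath), fs$frames)
})

test_that("front traces round-trip through CSV with provenance", {
  scene <- test_scene(r0 = 40, size = 96, n_frames = 3)
  tr <- simulate_front_trace(sqrt_law(), duration = 10, step = 5)
  fs <- render_frames(tr, scene)
  rec <- extract_front_trace(fs, roi = test_roi(scene))
  d <- withr::local_tempdir()
  p <- file.path(d, "trace.csv")
  write_front_trace(rec, p)
  expect_true(file.exists(file.path(d, "trace_provenance.json")))
  back <- read_front_trace(p)
  expect_equal(back$t, rec$t)
  expect_equal(back$s, rec$s)
  # corrupt header: error names the missing column
  bad <- file.path(d, "bad.csv")
  write.csv(data.frame(time = 1:3, length = 1:3), bad, row.names = FALSE)
  expect_error(read_front_trace(bad), "t_min")
})
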