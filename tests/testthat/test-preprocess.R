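test_that("background estimation is the per-pixel median", {
  frames <- replicate(50, matrix(0.3, 8, 10), simplify = FALSE)
  expect_equal(estimate_background(frames), matrix(0.3, 8, 10))

  # an outlier in 1 of 50 frames does not move the median
  frames <- replicate(50, matrix(0, 8, 10), simplify = FALSE)
  frames[[17]][3, 4] <- 10
  expect_equal(estimate_background(frames)[3, 4], 0)

  # n = 1 is the identity
  f1 <- matrix(rnorm(30), 5, 6)
  expect_equal(estimate_background(list(f1), n = 1), f1)

  # random stack against the brute-force per-pixel oracle
  set.seed(42)
  frames <- replicate(7, matrix(rnorm(48), 6, 8), simplify = FALSE)
  expect_equal(estimate_background(frames, n = 7),
               median_stack_oracle(frames))
})

test_that("a short stack triggers a warning and uses all frames", {
  frames <- replicate(5, matrix(rnorm(20), 4, 5), simplify = FALSE)
  expect_warning(bg <- estimate_background(frames, n = 50),
                 "only 5 frame")
  expect_equal(bg, median_stack_oracle(frames))
})

test_that("background subtraction is elementwise and shape-checked", {
  bg <- matrix(rnorm(24), 4, 6)
  expect_equal(unclass(subtract_background(bg, bg)),
               matrix(0, 4, 6), ignore_attr = TRUE)
  f <- matrix(rnorm(24), 4, 6)
  out <- subtract_background(f, bg)
  expect_equal(as.vector(out), as.vector(f) - as.vector(bg))
  expect_true(isTRUE(attr(out, "corrected")))
  # zero background is the identity
  expect_equal(as.vector(subtract_background(f, matrix(0, 4, 6))),
               as.vector(f))
  expect_error(subtract_background(f, matrix(0, 6, 4)),
               "4 x 6.*6 x 4")
})

test_that("segmentation finds thresholded 8-connected components", {
  expect_equal(segment_frame(matrix(0, 50, 50))$n_objects, 0)

  frame <- dome_frame(96, 96, c(48, 48), radius = 10, peak = 2)
  seg <- segment_frame(frame, threshold = 0.8)
  expect_equal(seg$n_objects, 1)
  # the labelled region must equal the flood fill of the thresholded mask
  mask <- frame > 0.8
  seed_px <- which(mask, arr.ind = TRUE)[1, ]
  expect_equal(seg$labels == 1, flood_fill8(mask, seed_px))

  two <- dome_frame(96, 96, c(30, 30), 8, 2) + dome_frame(96, 96, c(70, 70), 8, 2)
  expect_equal(segment_frame(two)$n_objects, 2)
})

test_that("diagonally touching pixels form one object (8-connectivity)", {
  f <- matrix(0, 20, 20)
  f[cbind(5:10, 5:10)] <- 2          # a pure diagonal line
  seg <- segment_frame(f)
  expect_equal(seg$n_objects, 1)
  # and a checkerboard pair stays joined to its block
  g <- matrix(0, 20, 20)
  g[5:8, 5:8] <- 2; g[9, 9] <- 2
  expect_equal(segment_frame(g)$n_objects, 1)
})

test_that("area filter is strictly greater than 30 px", {
  f30 <- matrix(0, 128, 128); f30[62:66, 62:67] <- 2   # 5 x 6 = 30 px
  seg <- segment_frame(f30)
  ex <- extract_patches(f30, seg)
  expect_equal(unname(ex$counts["kept"]), 0L)
  expect_equal(unname(ex$counts["rejected_small"]), 1L)

  f31 <- f30; f31[67, 62] <- 2                          # 31 px
  ex31 <- extract_patches(f31, segment_frame(f31))
  expect_equal(unname(ex31$counts["kept"]), 1L)
  expect_equal(ex31$patches[[1]]$area_px, 31L)
})

test_that("a centred dome in a 96 x 96 frame yields a patch equal to it", {
  frame <- dome_frame(96, 96, c(48, 48), radius = 12, peak = 2)
  ex <- extract_patches(frame, segment_frame(frame))
  expect_equal(length(ex$patches), 1)
  expect_identical(ex$patches[[1]]$patch, frame)
  expect_equal(unname(ex$patches[[1]]$centroid), c(48, 48))
})

test_that("cells whose patch window leaves the frame are border-rejected", {
  frame <- dome_frame(128, 128, c(10, 64), radius = 8, peak = 2)
  ex <- extract_patches(frame, segment_frame(frame))
  expect_equal(length(ex$patches), 0)
  expect_equal(unname(ex$counts["rejected_border"]), 1L)
})

test_that("raising the threshold never increases surviving contours", {
  sc <- small_scene(seed = 31, n_frames = 2, cells_per_frame = 4)
  pp0 <- suppressWarnings(preprocess_stack(sc))
  frame <- subtract_background(sc$frames[[1]],
                               estimate_background(sc$frames, n = 2))
  survivors <- vapply(c(0.8, 1.2, 1.6, 2.0, 5.9), function(th) {
    ex <- extract_patches(frame, segment_frame(frame, th), frame_id = 1)
    length(ex$patches) + unname(ex$counts["rejected_border"])
  }, numeric(1))
  expect_true(all(diff(survivors) <= 0))
})

test_that("synthetic cells are recovered with high recall and small
           centroid error", {
  sc <- small_scene(seed = 41, n_frames = 10, cells_per_frame = 5,
                    noise_sd = 0.05, frame_shape = c(256, 320))
  rec <- segmentation_recovery(sc)
  expect_gte(rec$recall, 0.99)
  expect_lte(max(rec$centroid_err), 2)
})

test_that("preprocessing an identical stack twice is fully deterministic", {
  sc <- small_scene(seed = 51, n_frames = 3, cells_per_frame = 3)
  a <- suppressWarnings(preprocess_stack(sc))
  b <- suppressWarnings(preprocess_stack(sc))
  expect_identical(a$index, b$index)
  expect_identical(a$patches, b$patches)
})
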