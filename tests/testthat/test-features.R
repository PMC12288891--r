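# build a cell_patch through the real segmentation path
patch_from_frame <- function(frame, threshold = 0.8) {
  ex <- extract_patches(frame, segment_frame(frame, threshold))
  stopifnot(length(ex$patches) == 1)
  ex$patches[[1]]
}

test_that("a digital disk has near-unit circularity and solidity", {
  frame <- dome_frame(128, 128, c(64, 64), radius = 12, peak = 2)
  # threshold 0.8 of a parabolic dome with peak 2 cuts at ~0.77 r: a disk of
  # radius ~9.3 px survives
  v <- compute_features(patch_from_frame(frame))
  expect_gte(v[["circularity"]], 0.85)
  expect_lte(v[["circularity"]], 1.0)
  expect_gte(v[["solidity"]], 0.95)
  expect_equal(v[["equivalent_diameter"]],
               2 * sqrt(v[["area_px"]] / pi))
})

test_that("a 5 x 1 bar is strongly elongated and eccentric", {
  frame <- matrix(0, 128, 128)
  frame[62:66, 64] <- 2
  ex <- extract_patches(frame, segment_frame(frame), min_area = 3)
  v <- compute_features(ex$patches[[1]])
  expect_gte(v[["aspect_ratio"]], 4)
  expect_gte(v[["eccentricity"]], 0.9)
  # hand-checked second moments of 5 collinear pixels with the 1/12 term:
  # major variance 2 + 1/12, minor 1/12 -> aspect ratio exactly 5
  expect_equal(v[["aspect_ratio"]], sqrt((2 + 1 / 12) / (1 / 12)))
})

test_that("uniform phase over a mask gives exact volume, mean and zero sd", {
  frame <- matrix(0, 128, 128)
  frame[60:69, 58:71] <- 1.7          # 10 x 14 rectangle, phase 1.7
  v <- compute_features(patch_from_frame(frame))
  expect_equal(v[["area_px"]], 140)
  expect_equal(v[["optical_volume"]], 1.7 * 140)
  expect_equal(v[["mean_phase"]], 1.7)
  expect_equal(v[["phase_sd"]], 0)
  expect_equal(v[["max_phase"]], 1.7)
  expect_equal(v[["extent"]], 1)
})

test_that("area, mean phase and optical volume match naive pixel loops", {
  sc <- small_scene(seed = 61, n_frames = 4, cells_per_frame = 4)
  pp <- suppressWarnings(preprocess_stack(sc))
  expect_gte(length(pp$patches), 10)
  for (p in pp$patches) {
    o <- patch_feature_oracle(p$patch, p$mask)
    v <- compute_features(p)
    expect_identical(v[["area_px"]], as.numeric(o$area))
    expect_equal(v[["optical_volume"]], o$volume, tolerance = 1e-12)
    expect_equal(v[["mean_phase"]], o$mean, tolerance = 1e-12)
  }
})

test_that("features are invariant to integer translation within the patch", {
  frame <- dome_frame(128, 128, c(60, 60), radius = 9, peak = 2.2,
                      elongation = 1.6, theta = 0.6)
  p <- patch_from_frame(frame)
  shifted <- p
  shift <- c(5, -7)
  shifted$patch <- matrix(0, 96, 96)
  shifted$mask <- matrix(FALSE, 96, 96)
  src_r <- which(rowSums(p$mask) > 0); src_c <- which(colSums(p$mask) > 0)
  pr <- range(which(p$patch != 0, arr.ind = TRUE)[, 1])
  pc <- range(which(p$patch != 0, arr.ind = TRUE)[, 2])
  shifted$patch[(pr[1]:pr[2]) + shift[1], (pc[1]:pc[2]) + shift[2]] <-
    p$patch[pr[1]:pr[2], pc[1]:pc[2]]
  shifted$mask[(pr[1]:pr[2]) + shift[1], (pc[1]:pc[2]) + shift[2]] <-
    p$mask[pr[1]:pr[2], pc[1]:pc[2]]
  shifted$contour <- p$contour + rep(shift, each = nrow(p$contour))
  va <- compute_features(p); vb <- compute_features(shifted)
  expect_equal(unclass(va), unclass(vb), tolerance = 1e-9)
})

test_that("90-degree rotation preserves size and phase features", {
  frame <- dome_frame(128, 128, c(64, 64), radius = 10, peak = 2,
                      elongation = 2, theta = 0.3)
  rot <- t(frame)[, nrow(frame):1]                 # 90 deg rotation
  va <- compute_features(patch_from_frame(frame))
  vb <- compute_features(patch_from_frame(rot))
  for (f in c("area_px", "optical_volume", "mean_phase", "max_phase"))
    expect_identical(va[[f]], vb[[f]])
  expect_equal(va[["circularity"]], vb[["circularity"]], tolerance = 1e-9)
  expect_equal(va[["solidity"]], vb[["solidity"]], tolerance = 1e-9)
  expect_equal(va[["aspect_ratio"]], vb[["aspect_ratio"]], tolerance = 1e-9)
})

test_that("doubling a disk's linear size quadruples area, keeps circularity", {
  digital_disk <- function(r) {
    n <- 128; ctr <- 64
    m <- matrix(0, n, n)
    rr <- matrix(seq_len(n), n, n); cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    m[(rr - ctr)^2 + (cc - ctr)^2 <= r^2] <- 2
    m
  }
  v1 <- compute_features(patch_from_frame(digital_disk(10)))
  v2 <- compute_features(patch_from_frame(digital_disk(20)))
  expect_equal(v2[["area_px"]] / v1[["area_px"]], 4, tolerance = 0.05)
  expect_equal(v2[["circularity"]], v1[["circularity"]], tolerance = 0.05)
})

test_that("degenerate masks fail QC with a reason", {
  p <- structure(list(patch = matrix(0, 96, 96), mask = matrix(FALSE, 96, 96),
                      contour = NULL, centroid = c(row = 1, col = 1),
                      area_px = 0L, frame_id = 1L, cell_id = 1L,
                      border_flag = FALSE), class = "cell_patch")
  v <- compute_features(p)
  expect_false(attr(v, "qc_pass"))
  expect_match(attr(v, "qc_reason"), "degenerate")
})

test_that("feature bounds filter exactly the out-of-range cells", {
  sc <- small_scene(seed = 71, n_frames = 3, cells_per_frame = 3)
  f <- compute_features(suppressWarnings(preprocess_stack(sc)))

  # empty bounds are the identity
  r0 <- apply_feature_bounds(f, feature_bounds())
  expect_identical(r0$kept, f)
  expect_equal(r0$n_rejected, 0)

  # a bound that every cell satisfies keeps everything
  r1 <- apply_feature_bounds(f, feature_bounds(area_px = c(31, 1e6)))
  expect_equal(nrow(r1$kept), nrow(f))

  # a bound excluding the largest cell rejects it with the feature named
  cut <- sort(f$area_px, decreasing = TRUE)[1] - 0.5
  r2 <- apply_feature_bounds(f, feature_bounds(area_px = c(31, cut)))
  expect_equal(nrow(r2$kept), nrow(f) - sum(f$area_px > cut))
  expect_true(all(r2$rejections$feature == "area_px"))

  expect_error(apply_feature_bounds(f, feature_bounds(no_such = c(0, 1))),
               "unknown feature")
})
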