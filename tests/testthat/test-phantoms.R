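test_that("an empty scene is background plus noise with empty truth", {
  spec <- scene_spec(frame_shape = c(64, 80), n_frames = 2,
                     cells_per_frame = 0, noise_sd_rad = 0, seed = 3)
  sc <- render_scene(spec, default_phenotype_models())
  expect_equal(nrow(sc$truth), 0)
  expect_identical(sc$frames[[1]], sc$background)
  expect_identical(sc$frames[[2]], sc$background)
})

test_that("the background field is static across frames of one stack", {
  sc <- small_scene(seed = 5, n_frames = 4, noise_sd = 0)
  # cells only add phase: the shared background is the pixelwise floor
  for (f in sc$frames) expect_true(all(f - sc$background >= -1e-12))
  # the same spec renders the same background in a fresh call
  sc2 <- small_scene(seed = 5, n_frames = 4, noise_sd = 0)
  expect_identical(sc$background, sc2$background)
})

test_that("a noiseless parabolic dome hits background + peak at its centre", {
  model <- phenotype_model("pure", 1,
                           radius_px = c(10, 0), elongation = c(1, 0),
                           peak_phase_rad = c(2.5, 0))
  spec <- scene_spec(frame_shape = c(128, 128), n_frames = 1,
                     cells_per_frame = 1, noise_sd_rad = 0,
                     margin_px = 20, seed = 11)
  sc <- render_scene(spec, list(model))
  ctr <- c(sc$truth$center_row, sc$truth$center_col)
  expect_equal(sc$frames[[1]][ctr[1], ctr[2]],
               sc$background[ctr[1], ctr[2]] + 2.5)
})

test_that("rendering is bit-identical for a fixed spec and seed", {
  a <- small_scene(seed = 9, n_frames = 2)
  b <- small_scene(seed = 9, n_frames = 2)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  c <- small_scene(seed = 10, n_frames = 2)
  expect_false(identical(a$frames, c$frames))
})

test_that("phase volume is conserved: frame minus background sums to the
           recorded cell volumes", {
  sc <- small_scene(seed = 21, n_frames = 3, cells_per_frame = 4,
                    noise_sd = 0)
  for (f in seq_along(sc$frames)) {
    rendered <- sum(sc$frames[[f]] - sc$background)
    truth_sum <- sum(sc$truth$volume_rad_px[sc$truth$frame_id == f])
    expect_equal(rendered, truth_sum, tolerance = 1e-6)
  }
})

test_that("truth masks of one frame never overlap when separation exceeds
           the maximum cell diameter", {
  model <- phenotype_model("round", 1, radius_px = c(9, 0.5),
                           elongation = c(1.1, 0.05),
                           peak_phase_rad = c(2.5, 0.2))
  spec <- scene_spec(frame_shape = c(256, 256), n_frames = 2,
                     cells_per_frame = 5, min_separation_px = 40,
                     noise_sd_rad = 0, seed = 2)
  sc <- render_scene(spec, list(model))
  for (f in unique(sc$truth$frame_id)) {
    rows <- which(sc$truth$frame_id == f)
    acc <- matrix(0L, 256, 256)
    for (i in rows)
      acc <- acc + decode_mask_rle(sc$masks[[i]], c(256, 256))
    expect_true(all(acc <= 1L))
  }
})

test_that("impossible placement fails with an error naming the frame", {
  spec <- scene_spec(frame_shape = c(60, 60), n_frames = 1,
                     cells_per_frame = 1, seed = 1)  # margin eats the frame
  expect_error(render_scene(spec, default_phenotype_models()), "frame 1")
  spec2 <- scene_spec(frame_shape = c(130, 130), n_frames = 1,
                      cells_per_frame = 30, min_separation_px = 50, seed = 1)
  expect_error(render_scene(spec2, default_phenotype_models()),
               "frame 1")
})

test_that("spike-in class allocation is deterministic and exact", {
  sc0 <- render_spike_in(0, 100, seed = 4, cells_per_frame = 10,
                         frame_shape = c(384, 512))
  expect_equal(sum(sc0$truth$label == "mesenchymal"), 0)
  expect_equal(sum(sc0$truth$label == "epithelial"), 100)

  sc25 <- render_spike_in(0.25, 1000, seed = 5)
  expect_equal(sum(sc25$truth$label == "mesenchymal"), 250)
  expect_equal(nrow(sc25$truth), 1000)
})

test_that("spike-in rounding follows round-half-even", {
  # 0.5 * 7 = 3.5 rounds to 4 under round-half-even (R's round())
  sc <- render_spike_in(0.5, 7, seed = 6, cells_per_frame = 7,
                        frame_shape = c(384, 512))
  expect_equal(sum(sc$truth$label == "mesenchymal"), 4)
  # 0.5 * 5 = 2.5 rounds to 2
  sc2 <- render_spike_in(0.5, 5, seed = 6, cells_per_frame = 5,
                         frame_shape = c(384, 512))
  expect_equal(sum(sc2$truth$label == "mesenchymal"), 2)
})

test_that("phenotype model validation rejects out-of-range parameters", {
  expect_error(phenotype_model("x", 0.5, elongation = c(0.8, 0.1)),
               "elongation")
  expect_error(phenotype_model("x", 0.5, peak_phase_rad = c(7, 0.1)),
               "peak_phase_rad")
  expect_error(render_scene(scene_spec(n_frames = 1),
                            list(phenotype_model("a", 0.4),
                                 phenotype_model("b", 0.4))),
               "sum to 1")
})

test_that("frames, truth and masks round-trip through the on-disk format", {
  sc <- small_scene(seed = 13, n_frames = 2, cells_per_frame = 2)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("frames.tif", "frames_scale.json", "truth.csv", "masks.csv")))))
  back <- read_frames(file.path(dir, "frames.tif"))
  expect_equal(length(back), 2)
  # 16-bit quantization over the 8-rad range: ~1.2e-4 rad per step
  expect_lt(max(abs(back[[1]] - sc$frames[[1]])), 2e-4)
  md <- read.csv(file.path(dir, "masks.csv"))
  m1 <- decode_mask_rle(md$rle[1], c(md$height[1], md$width[1]))
  expect_equal(sum(m1), sum(decode_mask_rle(sc$masks[[1]],
                                            dim(sc$frames[[1]]))))
})
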