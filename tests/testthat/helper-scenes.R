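# Small synthetic scenes shared across test files. Frames are kept well
# below the native 384 x 512 geometry so each test renders in milliseconds.

small_scene <- function(seed = 1, n_frames = 3, cells_per_frame = 3,
                        noise_sd = 0.05, frame_shape = c(192, 256),
                        models = default_phenotype_models(), ...) {
  render_scene(scene_spec(frame_shape = frame_shape, n_frames = n_frames,
                          cells_per_frame = cells_per_frame,
                          noise_sd_rad = noise_sd, seed = seed, ...),
               models)
}

# deterministic single-dome frame on a zero background: parabolic dome of
# known peak at an exact pixel centre
dome_frame <- function(h = 96, w = 96, center = c(48, 48), radius = 10,
                       peak = 2, elongation = 1, theta = 0) {
  frame <- matrix(0, h, w)
  a <- radius * sqrt(elongation); b <- radius / sqrt(elongation)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  u <- rr - center[1]; v <- cc - center[2]
  q <- ((u * cos(theta) + v * sin(theta)) / a)^2 +
       ((-u * sin(theta) + v * cos(theta)) / b)^2
  frame + peak * pmax(0, 1 - q)
}

# features + true labels for a scene, via preprocessing and truth matching
scene_features <- function(scene, background_n = length(scene$frames)) {
  pp <- suppressWarnings(preprocess_stack(scene, background_n = background_n))
  f <- compute_features(pp)
  m <- match_to_truth(pp, scene)
  f$label <- m$label
  f[!is.na(f$label) & f$qc_pass, , drop = FALSE]
}

feature_cols <- dhm_feature_names()
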