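# Independent oracles, deliberately naive: these re-derive quantities by
# brute force so package internals are checked against a second route.

# 8-connected flood fill from one seed pixel over a logical mask
flood_fill8 <- function(mask, seed_px) {
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- list(seed_px)
  visited[seed_px[1], seed_px[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
          mask[r, c] && !visited[r, c]) {
        visited[r, c] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  visited
}

# per-pixel median across a list of frames, the slow way
median_stack_oracle <- function(frames) {
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  out <- matrix(NA_real_, h, w)
  for (r in seq_len(h)) for (c in seq_len(w))
    out[r, c] <- median(vapply(frames, function(f) f[r, c], numeric(1)))
  out
}

# naive per-pixel accumulation of mask area, mean phase and optical volume
patch_feature_oracle <- function(patch, mask) {
  area <- 0L; s <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) { area <- area + 1L; s <- s + patch[r, c] }
  list(area = area, volume = s, mean = s / area)
}

# segmentation recall / centroid error against a scene's truth table
segmentation_recovery <- function(scene, max_dist = 5) {
  pp <- suppressWarnings(preprocess_stack(scene))
  m <- match_to_truth(pp, scene, max_dist = max_dist)
  list(recall = sum(!is.na(m$truth_row)) / nrow(scene$truth),
       centroid_err = m$match_dist[!is.na(m$match_dist)])
}
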