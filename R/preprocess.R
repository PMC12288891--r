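#' Estimate the static background of an acquisition
#'
#' The instrument's lens, camera, light source and microfluidic channel are
#' fixed within one capture, so the background is static. It is estimated as
#' the per-pixel median over the first `n` frames (default 50) and reused for
#' every frame of the acquisition.
#'
#' @param frames list of phase matrices (one acquisition, uniform shape).
#' @param n number of leading frames to use; if fewer are available, all
#'   frames are used with a warning.
#' @return background matrix (per-pixel median).
#' @export
#' @examples
#' frames <- replicate(5, matrix(0.3, 4, 4), simplify = FALSE)
#' estimate_background(frames, n = 5)[1, 1]
estimate_background <- function(frames, n = 50L) {
  stopifnot(is.list(frames), length(frames) >= 1, n >= 1)
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("frames must share one shape within an acquisition")
  if (length(frames) < n) {
    warning("only ", length(frames), " frame(s) available for background ",
            "estimation (requested n = ", n, "); using all of them")
    n <- length(frames)
  }
  use <- frames[seq_len(n)]
  h <- nrow(use[[1]]); w <- ncol(use[[1]])
  if (n == 1) return(use[[1]])
  X <- matrix(unlist(use, use.names = FALSE), nrow = h * w)
  matrix(row_medians(X), h, w)
}

#' Subtract the static background from a frame
#'
#' Plain pixelwise subtraction, no clipping; removes the channel's optical
#' artifacts and fixed-pattern noise ahead of thresholding.
#'
#' @param frame phase matrix.
#' @param background background matrix of identical shape.
#' @return corrected matrix with attribute `corrected = TRUE`.
#' @export
subtract_background <- function(frame, background) {
  if (!identical(dim(frame), dim(background)))
    stop("shape mismatch: frame is ", paste(dim(frame), collapse = " x "),
         ", background is ", paste(dim(background), collapse = " x "))
  out <- frame - background
  attr(out, "corrected") <- TRUE
  out
}

## exact 8-connectivity from EBImage's 4-connected labelling: union-find merge
## of label pairs that touch diagonally, then renumber components by the
## column-major position of their first pixel (deterministic scan order)
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n > 1) {
    h <- nrow(lab); w <- ncol(lab)
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]       # down-right diagonal
    a2 <- lab[-1, -w]; b2 <- lab[-h, -1]       # up-right diagonal
    s1 <- a1 > 0L & b1 > 0L & a1 != b1
    s2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  ids <- unique(lab[lab > 0L])            # column-major first-pixel order
  if (length(ids)) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Segment a background-corrected frame by binary thresholding
#'
#' Pixels above `threshold` (strict inequality) form the foreground; its
#' 8-connected components are the cell candidates, and each component's outer
#' border is extracted by border following. Holes inside a cell are ignored
#' (outer contours only). Objects are numbered in the order of their first
#' pixel in a column-major scan of the frame.
#'
#' @param frame background-corrected phase matrix.
#' @param threshold phase threshold in radians (default 0.8).
#' @return object of class `dhm_segmentation`: `labels` (integer matrix, 0 =
#'   background), `contours` (list of n x 2 matrices of 1-based
#'   `(row, col)` border coordinates, one per object), `threshold`,
#'   `n_objects`.
#' @export
segment_frame <- function(frame, threshold = 0.8) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  mask <- frame > threshold
  lab <- label_components(mask)
  n <- max(lab)
  contours <- if (n > 0) {
    oc <- EBImage::ocontour(lab)
    lapply(seq_len(n), function(i) {
      m <- oc[[as.character(i)]] %||% oc[[i]]
      m + 1L                               # ocontour is 0-based
    })
  } else list()
  structure(list(labels = lab, contours = contours,
                 threshold = threshold, n_objects = n),
            class = "dhm_segmentation")
}

#' @export
print.dhm_segmentation <- function(x, ...) {
  cat("<dhm_segmentation>", x$n_objects, "object(s) at threshold",
      x$threshold, "rad\n")
  invisible(x)
}

#' Filter contours and extract single-cell patches
#'
#' Keeps only objects whose enclosed pixel area is strictly greater than
#' `min_area` (default 30 px), and stores each with the `patch_px` x
#' `patch_px` phase window centred on the object's area centroid (centre
#' pixel = floor of the centroid). Objects whose window would cross a frame
#' edge are dropped and counted as border rejections, since truncated cells
#' corrupt morphology features.
#'
#' @param frame background-corrected phase matrix (same frame as `seg`).
#' @param seg a `dhm_segmentation` from [segment_frame()].
#' @param min_area area filter in pixels; strictly-greater-than comparison.
#' @param patch_px patch side (even; default 96).
#' @param frame_id provenance id stored with each patch.
#' @return list: `patches` (list of `cell_patch` objects: `patch`, `mask`,
#'   `contour` in frame coordinates, `centroid`, `area_px`, `frame_id`,
#'   `cell_id`), and `counts` (`n_contours`, `kept`, `rejected_small`,
#'   `rejected_border`).
#' @export
extract_patches <- function(frame, seg, min_area = 30L, patch_px = 96L,
                            frame_id = 1L) {
  stopifnot(inherits(seg, "dhm_segmentation"), patch_px %% 2 == 0)
  lab <- seg$labels
  n <- seg$n_objects
  counts <- c(n_contours = n, kept = 0L, rejected_small = 0L,
              rejected_border = 0L)
  if (n == 0) return(list(patches = list(), counts = counts))
  idx <- which(lab > 0L)
  obj <- lab[idx]
  areas <- tabulate(obj, nbins = n)
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  cr <- unname(rowsum(as.numeric(rows), obj)[, 1]) / areas
  cc <- unname(rowsum(as.numeric(cols), obj)[, 1]) / areas
  half_lo <- patch_px %/% 2L - 1L          # 47 rows/cols above-left of centre
  half_hi <- patch_px %/% 2L               # 48 below-right
  patches <- list()
  cell_id <- 0L
  for (i in seq_len(n)) {
    if (areas[i] <= min_area) {
      counts["rejected_small"] <- counts["rejected_small"] + 1L
      next
    }
    r0 <- floor(cr[i]) - half_lo; r1 <- floor(cr[i]) + half_hi
    c0 <- floor(cc[i]) - half_lo; c1 <- floor(cc[i]) + half_hi
    if (r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame)) {
      counts["rejected_border"] <- counts["rejected_border"] + 1L
      next
    }
    cell_id <- cell_id + 1L
    patches[[cell_id]] <- structure(
      list(patch = frame[r0:r1, c0:c1],
           mask = lab[r0:r1, c0:c1] == i,
           contour = seg$contours[[i]],
           centroid = c(row = cr[i], col = cc[i]),
           area_px = areas[i],
           frame_id = frame_id, cell_id = cell_id,
           border_flag = FALSE),
      class = "cell_patch")
  }
  counts["kept"] <- cell_id
  list(patches = patches, counts = counts)
}

#' Run the full pre-processing chain on a frame stack
#'
#' Estimates the static background from the first `background_n` frames,
#' subtracts it from every frame, segments each corrected frame at
#' `threshold`, and extracts filtered single-cell patches.
#'
#' @param frames list of raw phase matrices, or a `dhm_scene`.
#' @param background_n frames used for the background median (default 50).
#' @param threshold segmentation threshold in radians (default 0.8).
#' @param min_area strict area filter in pixels (default 30).
#' @param patch_px patch side in pixels (default 96).
#' @return object of class `dhm_patches`: `patches` (flat list of
#'   `cell_patch`), `index` (data frame: `frame_id`, `cell_id`,
#'   `centroid_row`, `centroid_col`, `area_px`), `counts` (frames, contours,
#'   survivors, rejections), `params`.
#' @export
#' @examples
#' sc <- render_scene(scene_spec(frame_shape = c(160, 160), n_frames = 3,
#'                               cells_per_frame = 2, seed = 3),
#'                    default_phenotype_models())
#' pp <- preprocess_stack(sc, background_n = 3)
#' pp$counts
preprocess_stack <- function(frames, background_n = 50L, threshold = 0.8,
                             min_area = 30L, patch_px = 96L) {
  if (inherits(frames, "dhm_scene")) frames <- frames$frames
  bg <- estimate_background(frames, n = background_n)
  patches <- list()
  index <- list()
  totals <- c(n_contours = 0L, kept = 0L, rejected_small = 0L,
              rejected_border = 0L)
  for (f in seq_along(frames)) {
    corrected <- subtract_background(frames[[f]], bg)
    seg <- segment_frame(corrected, threshold = threshold)
    ex <- extract_patches(corrected, seg, min_area = min_area,
                          patch_px = patch_px, frame_id = f)
    totals <- totals + ex$counts
    for (p in ex$patches) {
      patches[[length(patches) + 1L]] <- p
      index[[length(index) + 1L]] <- data.frame(
        frame_id = f, cell_id = p$cell_id,
        centroid_row = p$centroid[["row"]],
        centroid_col = p$centroid[["col"]],
        area_px = p$area_px)
    }
  }
  index <- if (length(index)) do.call(rbind, index)
           else data.frame(frame_id = integer(0), cell_id = integer(0),
                           centroid_row = numeric(0), centroid_col = numeric(0),
                           area_px = integer(0))
  structure(list(patches = patches, index = index,
                 counts = c(frames = length(frames), totals),
                 background = bg,
                 params = list(background_n = background_n,
                               threshold = threshold, min_area = min_area,
                               patch_px = patch_px)),
            class = "dhm_patches")
}

#' @export
print.dhm_patches <- function(x, ...) {
  cat("<dhm_patches>", length(x$patches), "cell patch(es) from",
      x$counts[["frames"]], "frame(s)\n")
  cat("  contours:", x$counts[["n_contours"]],
      " small-rejected:", x$counts[["rejected_small"]],
      " border-rejected:", x$counts[["rejected_border"]], "\n")
  invisible(x)
}

#' Match detected cells to ground-truth cells of a synthetic scene
#'
#' Greedy nearest-centre matching between a detection index and a scene's
#' truth table, frame by frame; used to attach true labels to detected cells
#' and to score segmentation recall.
#'
#' @param index detection index (`frame_id`, `centroid_row`, `centroid_col`),
#'   e.g. `preprocess_stack(...)$index`, or a `dhm_patches` object.
#' @param truth truth data frame of a `dhm_scene` (or the scene itself).
#' @param max_dist maximum centre distance (px) for a valid match.
#' @return `index` with columns `label`, `truth_row` (row number in `truth`)
#'   and `match_dist`; unmatched detections carry `NA`.
#' @export
match_to_truth <- function(index, truth, max_dist = 10) {
  if (inherits(index, "dhm_patches")) index <- index$index
  if (inherits(truth, "dhm_scene")) truth <- truth$truth
  index$label <- NA_character_
  index$truth_row <- NA_integer_
  index$match_dist <- NA_real_
  for (f in unique(index$frame_id)) {
    di <- which(index$frame_id == f)
    ti <- which(truth$frame_id == f)
    if (!length(ti)) next
    d2 <- outer(index$centroid_row[di], truth$center_row[ti], "-")^2 +
          outer(index$centroid_col[di], truth$center_col[ti], "-")^2
    taken <- logical(length(ti))
    ord <- order(d2)
    for (k in ord) {
      i <- ((k - 1) %% length(di)) + 1
      j <- ((k - 1) %/% length(di)) + 1
      if (taken[j] || !is.na(index$truth_row[di[i]])) next
      if (d2[i, j] > max_dist^2) break
      index$truth_row[di[i]] <- ti[j]
      index$label[di[i]] <- truth$label[ti[j]]
      index$match_dist[di[i]] <- sqrt(d2[i, j])
      taken[j] <- TRUE
    }
  }
  index
}
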