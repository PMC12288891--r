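#' Names of the morphological feature bank
#'
#' Version `"v1"` is a 15-feature bank spanning the size, shape and
#' phase-content axes of suspended-cell morphology: pixel area, polygonal
#' contour perimeter, circularity, equivalent diameter, best-fit-ellipse
#' aspect ratio and eccentricity (from second-order mask moments, with the
#' 1/12 unit-square pixel term), solidity (area over convex-hull lattice
#' area), extent (area over bounding-box area), mean/max/sd of phase over
#' the mask, optical volume (summed phase), phase skewness, radial
#' mean-profile slope, and mean phase-gradient magnitude.
#'
#' @param version feature-set version identifier.
#' @return character vector of feature names, in fixed order.
#' @export
dhm_feature_names <- function(version = "v1") {
  if (!identical(version, "v1")) stop("unknown feature_set_version: ", version)
  c("area_px", "perimeter_px", "circularity", "equivalent_diameter",
    "aspect_ratio", "eccentricity", "solidity", "extent",
    "mean_phase", "max_phase", "phase_sd", "optical_volume",
    "phase_skewness", "radial_profile_slope", "gradient_mag_mean")
}

## polygon perimeter of a closed contour given as (row, col) vertices
contour_perimeter <- function(contour) {
  if (is.null(contour) || nrow(contour) < 2) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  sum(sqrt(rowSums((contour - nxt)^2)))
}

## lattice-pixel count of the convex hull of mask pixels via Pick's theorem:
## points on or inside hull = shoelace area + boundary lattice points/2 + 1
convex_hull_px <- function(rows, cols) {
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) <= 2) return(nrow(pts))
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull, , drop = FALSE]
  nxt <- rbind(hp[-1, , drop = FALSE], hp[1, , drop = FALSE])
  area <- abs(sum(hp[, 2] * nxt[, 1] - nxt[, 2] * hp[, 1])) / 2
  edges <- nxt - hp
  boundary <- sum(mapply(function(a, b) {
    a <- abs(a); b <- abs(b)
    if (a == 0 && b == 0) 0L else {
      while (b > 0) { t <- a %% b; a <- b; b <- t }
      a
    }
  }, edges[, 1], edges[, 2]))
  area + boundary / 2 + 1
}

#' Compute morphological features for a cell patch
#'
#' @param x a `cell_patch` (from [extract_patches()] / [preprocess_stack()])
#'   or a `dhm_patches` collection.
#' @param version feature-set version (see [dhm_feature_names()]).
#' @param ... unused.
#' @return For a single patch, a named numeric vector in the fixed feature
#'   order with attribute `qc_pass` (FALSE, with attribute `qc_reason`, when
#'   the mask is degenerate, i.e. below 3 px). For a collection, a data
#'   frame with provenance columns `frame_id`, `cell_id`, the features, and
#'   `qc_pass`.
#' @export
#' @examples
#' patch <- matrix(0, 96, 96)
#' patch[44:52, 44:52] <- 2
#' cp <- structure(list(patch = patch, mask = patch > 0, contour = NULL,
#'                      centroid = c(row = 48, col = 48), area_px = 81,
#'                      frame_id = 1L, cell_id = 1L, border_flag = FALSE),
#'                 class = "cell_patch")
#' round(compute_features(cp)[c("area_px", "mean_phase", "optical_volume")], 3)
compute_features <- function(x, ...) UseMethod("compute_features")

#' @rdname compute_features
#' @export
compute_features.cell_patch <- function(x, version = "v1", ...) {
  nm <- dhm_feature_names(version)
  vals <- stats::setNames(rep(NA_real_, length(nm)), nm)
  mask <- x$mask
  area <- sum(mask)
  if (area < 3) {
    attr(vals, "qc_pass") <- FALSE
    attr(vals, "qc_reason") <- paste0("degenerate mask (", area, " px)")
    return(vals)
  }
  idx <- which(mask)
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  phase <- x$patch[idx]

  vals["area_px"] <- area
  ## contour may live in frame coordinates; perimeter is shift-invariant
  per <- contour_perimeter(x$contour)
  vals["perimeter_px"] <- per
  vals["circularity"] <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  vals["equivalent_diameter"] <- 2 * sqrt(area / pi)

  ## second-order central moments with the unit-square pixel term 1/12
  rb <- mean(rows); cb <- mean(cols)
  mrr <- mean((rows - rb)^2) + 1 / 12
  mcc <- mean((cols - cb)^2) + 1 / 12
  mrc <- mean((rows - rb) * (cols - cb))
  tr2 <- (mrr + mcc) / 2
  det4 <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
  l1 <- tr2 + det4; l2 <- max(tr2 - det4, .Machine$double.eps)
  vals["aspect_ratio"] <- sqrt(l1 / l2)
  vals["eccentricity"] <- sqrt(max(0, 1 - l2 / l1))

  vals["solidity"] <- area / convex_hull_px(rows, cols)
  bb <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1)
  vals["extent"] <- area / bb

  vals["mean_phase"] <- mean(phase)
  vals["max_phase"] <- max(phase)
  vals["phase_sd"] <- stats::sd(phase)
  vals["optical_volume"] <- sum(phase)
  m2 <- mean((phase - mean(phase))^2)
  vals["phase_skewness"] <- if (m2 > 1e-12)
    mean((phase - mean(phase))^3) / m2^1.5 else 0

  d <- sqrt((rows - rb)^2 + (cols - cb)^2)
  vd <- stats::var(d)
  vals["radial_profile_slope"] <- if (is.finite(vd) && vd > 1e-12)
    stats::cov(d, phase) / vd else 0

  ## central-difference gradient over the patch, averaged within the mask
  p <- x$patch
  gr <- (rbind(p[-1, ], p[nrow(p), ]) - rbind(p[1, ], p[-nrow(p), ])) / 2
  gc <- (cbind(p[, -1], p[, ncol(p)]) - cbind(p[, 1], p[, -ncol(p)])) / 2
  vals["gradient_mag_mean"] <- mean(sqrt(gr[idx]^2 + gc[idx]^2))

  attr(vals, "qc_pass") <- all(is.finite(vals))
  vals
}

#' @rdname compute_features
#' @export
compute_features.dhm_patches <- function(x, version = "v1", ...) {
  nm <- dhm_feature_names(version)
  n <- length(x$patches)
  out <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  qc <- logical(n)
  for (i in seq_len(n)) {
    v <- compute_features(x$patches[[i]], version = version)
    out[i, ] <- v
    qc[i] <- isTRUE(attr(v, "qc_pass"))
  }
  cbind(data.frame(frame_id = x$index$frame_id %||% integer(0),
                   cell_id = x$index$cell_id %||% integer(0)),
        as.data.frame(out), data.frame(qc_pass = qc))
}

#' @rdname compute_features
#' @export
compute_features.list <- function(x, version = "v1", ...) {
  stopifnot(all(vapply(x, inherits, logical(1), "cell_patch")))
  do.call(rbind, lapply(x, function(p) {
    v <- compute_features(p, version = version)
    cbind(data.frame(frame_id = p$frame_id, cell_id = p$cell_id),
          as.data.frame(as.list(v)),
          data.frame(qc_pass = isTRUE(attr(v, "qc_pass"))))
  }))
}

#' Build a feature-bounds table
#'
#' @param ... named arguments, each a length-2 numeric `c(lower, upper)`
#'   (use `-Inf`/`Inf` for open ends), e.g.
#'   `feature_bounds(area_px = c(31, 5000))`.
#' @return data frame with columns `feature`, `lower`, `upper`.
#' @export
feature_bounds <- function(...) {
  b <- list(...)
  if (!length(b)) return(data.frame(feature = character(0),
                                    lower = numeric(0), upper = numeric(0)))
  stopifnot(!is.null(names(b)), all(nzchar(names(b))),
            all(vapply(b, length, integer(1)) == 2))
  out <- data.frame(feature = names(b),
                    lower = vapply(b, `[`, numeric(1), 1),
                    upper = vapply(b, `[`, numeric(1), 2))
  if (any(out$lower > out$upper)) stop("lower bound exceeds upper bound")
  out
}

#' Filter cells by per-feature validity bounds
#'
#' A cell is kept iff every bounded feature lies inside its closed
#' `[lower, upper]` interval. No bounds are active by default anywhere in the
#' pipeline (the 30-px area floor is enforced upstream), so nothing is
#' silently dropped.
#'
#' @param features feature data frame (one row per cell).
#' @param bounds data frame from [feature_bounds()] (may have zero rows).
#' @return list: `kept` (filtered data frame), `rejections` (data frame
#'   `row`, `feature` with one entry per violated bound), `n_rejected`.
#' @export
apply_feature_bounds <- function(features, bounds) {
  stopifnot(is.data.frame(features), is.data.frame(bounds))
  unknown <- setdiff(bounds$feature, names(features))
  if (length(unknown))
    stop("bounds reference unknown feature(s): ",
         paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(features))
  rej <- list()
  for (i in seq_len(nrow(bounds))) {
    f <- bounds$feature[i]
    bad <- !(features[[f]] >= bounds$lower[i] & features[[f]] <= bounds$upper[i])
    bad[is.na(bad)] <- TRUE
    if (any(bad)) rej[[length(rej) + 1L]] <-
      data.frame(row = which(bad), feature = f)
    keep <- keep & !bad
  }
  rejections <- if (length(rej)) do.call(rbind, rej)
                else data.frame(row = integer(0), feature = character(0))
  list(kept = features[keep, , drop = FALSE],
       rejections = rejections,
       n_rejected = sum(!keep))
}
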