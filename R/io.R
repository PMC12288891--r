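#' Write a phase-frame stack as multi-page TIFF
#'
#' Frames are stored as 16-bit TIFF with an affine phase scale recorded in a
#' JSON sidecar (`<stem>_scale.json`): `phase = offset + scale * stored`.
#' The default range covers the interval DHM phase images typically occupy,
#' -2 to 6 rad, giving a quantization step of about 1.2e-4 rad.
#'
#' @param frames list of numeric matrices (radians) or a `dhm_scene`.
#' @param path output TIFF path.
#' @param range phase values mapped to the 16-bit range; values outside are
#'   clipped (with a warning).
#' @return `path`, invisibly.
#' @seealso [read_frames()]
#' @export
write_frames <- function(frames, path, range = c(-2, 6)) {
  if (inherits(frames, "dhm_scene")) frames <- frames$frames
  stopifnot(length(frames) >= 1, range[2] > range[1])
  lo <- range[1]; span <- range[2] - range[1]
  scaled <- lapply(frames, function(f) {
    s <- (f - lo) / span
    if (any(s < 0 | s > 1)) {
      warning("phase values outside [", lo, ", ", range[2], "] rad clipped")
      s <- pmin(1, pmax(0, s))
    }
    s
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, reduce = FALSE)
  sidecar <- sub("\\.tiff?$", "", path)
  jsonlite::write_json(list(phase_min = lo, phase_max = range[2],
                            n_frames = length(frames)),
                       paste0(sidecar, "_scale.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a phase-frame stack written by [write_frames()]
#'
#' @param path TIFF path; the `<stem>_scale.json` sidecar written alongside
#'   it supplies the affine phase scale. Without a sidecar, `range` is used.
#' @param range fallback phase range when no sidecar is present.
#' @return list of numeric matrices in radians.
#' @export
read_frames <- function(path, range = c(-2, 6)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(sub("\\.tiff?$", "", path), "_scale.json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar)
    lo <- sc$phase_min; hi <- sc$phase_max
  } else {
    lo <- range[1]; hi <- range[2]
  }
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    lo + (hi - lo) * p
  })
}

#' Write a scene's ground truth and masks to plain-text sidecars
#'
#' Writes `truth.csv` (one row per cell) and `masks.csv` (per-cell
#' run-length-encoded support masks over the column-major pixel index).
#'
#' @param scene a `dhm_scene`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "dhm_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frames(scene$frames, file.path(dir, "frames.tif"))
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  md <- data.frame(frame_id = scene$truth$frame_id,
                   cell_id = scene$truth$cell_id,
                   height = scene$spec$frame_shape[1],
                   width = scene$spec$frame_shape[2],
                   rle = unlist(scene$masks))
  utils::write.csv(md, file.path(dir, "masks.csv"), row.names = FALSE)
  invisible(dir)
}
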