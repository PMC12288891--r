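#' Define a synthetic cell phenotype model
#'
#' A phenotype model describes one morphological population of suspended
#' cells as seen by quantitative phase imaging: an elliptical footprint with
#' a smooth phase dome on top. Cells are drawn by sampling an equivalent
#' radius, an axis ratio (elongation), and a peak phase height, then rotating
#' the ellipse uniformly at random. Round, compact, optically dense models
#' mimic epithelial cells; elongated, flatter models mimic spindle-shaped
#' mesenchymal cells.
#'
#' @param name label of the population (e.g. `"epithelial"`).
#' @param count_fraction expected proportion of cells from this model in a
#'   mixed scene; fractions over all models of a scene must sum to 1.
#' @param radius_px mean and sd of the equivalent circular radius in pixels.
#'   Sampled radii are truncated below at 3 px.
#' @param elongation mean and sd of the major/minor axis ratio; truncated
#'   below at 1 (a circle).
#' @param peak_phase_rad mean and sd of the phase at the dome centre, in
#'   radians; truncated to (0, 6]. The mean must lie in (0, 6], the range DHM
#'   phase images occupy.
#' @param profile radial phase profile: `"parabolic"` (dome
#'   `peak * (1 - q)` on the ellipse `q <= 1`) or `"gaussian"`
#'   (`peak * exp(-q/2)` truncated at `q = 9`).
#' @return an object of class `phenotype_model`.
#' @seealso [default_phenotype_models()], [render_scene()]
#' @export
phenotype_model <- function(name, count_fraction,
                            radius_px = c(mean = 10, sd = 1),
                            elongation = c(mean = 1.2, sd = 0.1),
                            peak_phase_rad = c(mean = 2.5, sd = 0.3),
                            profile = c("parabolic", "gaussian")) {
  profile <- match.arg(profile)
  stopifnot(is.character(name), nzchar(name),
            count_fraction >= 0, count_fraction <= 1,
            length(radius_px) == 2, radius_px[1] > 0, radius_px[2] >= 0,
            length(elongation) == 2, elongation[2] >= 0,
            length(peak_phase_rad) == 2, peak_phase_rad[2] >= 0)
  if (elongation[1] < 1)
    stop("elongation mean must be >= 1 (major/minor axis ratio)")
  if (peak_phase_rad[1] <= 0 || peak_phase_rad[1] > 6)
    stop("peak_phase_rad mean must lie in (0, 6] rad")
  structure(list(name = name, count_fraction = count_fraction,
                 radius_px = unname(radius_px),
                 elongation = unname(elongation),
                 peak_phase_rad = unname(peak_phase_rad),
                 profile = profile),
            class = "phenotype_model")
}

#' Default epithelial / mesenchymal phantom populations
#'
#' The two default populations span the round-vs-spindle morphology axis that
#' phenotype classifiers must separate: epithelial cells are larger, nearly
#' round and optically dense; mesenchymal cells are smaller in equivalent
#' radius, strongly elongated and flatter. An optional hybrid population sits
#' between the two. Parameter values are the package's documented defaults
#' (see the methods vignette); they are not measurements of any cell line.
#'
#' @param p_mesenchymal expected mesenchymal fraction (the epithelial
#'   fraction is its complement; a hybrid, when included, takes an equal
#'   share from both).
#' @param include_hybrid include a third, intermediate population.
#' @return list of [phenotype_model()] objects.
#' @export
#' @examples
#' models <- default_phenotype_models()
#' vapply(models, `[[`, character(1), "name")
default_phenotype_models <- function(p_mesenchymal = 0.5, include_hybrid = FALSE) {
  stopifnot(p_mesenchymal >= 0, p_mesenchymal <= 1)
  epi <- phenotype_model("epithelial", 1 - p_mesenchymal,
                         radius_px = c(11, 1.2),
                         elongation = c(1.15, 0.10),
                         peak_phase_rad = c(2.6, 0.30))
  mes <- phenotype_model("mesenchymal", p_mesenchymal,
                         radius_px = c(8, 1.0),
                         elongation = c(3.0, 0.45),
                         peak_phase_rad = c(1.8, 0.25))
  if (!include_hybrid) return(list(epi, mes))
  hyb <- phenotype_model("hybrid", 0,
                         radius_px = c(9.5, 1.1),
                         elongation = c(1.9, 0.35),
                         peak_phase_rad = c(2.2, 0.30))
  epi$count_fraction <- (1 - p_mesenchymal) * 2 / 3
  mes$count_fraction <- p_mesenchymal * 2 / 3
  hyb$count_fraction <- 1 - epi$count_fraction - mes$count_fraction
  list(epi, mes, hyb)
}

#' Specify the geometry and nuisance structure of a synthetic acquisition
#'
#' @param frame_shape `c(height_px, width_px)` of each frame; the default is
#'   the native DHM frame geometry (384 rows by 512 columns).
#' @param n_frames number of frames in the stack.
#' @param cells_per_frame cells placed in each frame.
#' @param noise_sd_rad per-pixel Gaussian shot-noise sd, radians.
#' @param min_separation_px minimum centre-to-centre distance between cells.
#' @param margin_px cells are placed at least this far (centre) from every
#'   frame edge; the default 52 keeps every default cell's footprint, and its
#'   96 x 96 patch window, fully inside the frame.
#' @param background list describing the static artifact field shared by all
#'   frames of the stack: `amplitude` (rad) of a smooth low-frequency field,
#'   `n_blemishes` fixed localized blemishes of `blemish_amplitude` (rad)
#'   and width `blemish_sigma` (px).
#' @param seed integer; the same spec and seed reproduce the stack
#'   bit-identically.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(frame_shape = c(384L, 512L), n_frames = 10L,
                       cells_per_frame = 12L, noise_sd_rad = 0.05,
                       min_separation_px = 36, margin_px = 52,
                       background = list(amplitude = 0.3, n_blemishes = 6,
                                         blemish_amplitude = 0.4,
                                         blemish_sigma = 3),
                       seed = 1L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape > 0),
            n_frames >= 0, cells_per_frame >= 0, noise_sd_rad >= 0,
            min_separation_px > 0, margin_px >= 0)
  bg <- list(amplitude = 0.3, n_blemishes = 6,
             blemish_amplitude = 0.4, blemish_sigma = 3)
  bg[names(background)] <- background
  structure(list(frame_shape = as.integer(frame_shape),
                 n_frames = as.integer(n_frames),
                 cells_per_frame = as.integer(cells_per_frame),
                 noise_sd_rad = noise_sd_rad,
                 min_separation_px = min_separation_px,
                 margin_px = margin_px, background = bg,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## static background: a few low-frequency cosine products plus fixed blemishes
make_background <- function(spec) {
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  bgspec <- spec$background
  with_seed(derive_seed(spec$seed, "background"), {
    bg <- matrix(0, h, w)
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    if (bgspec$amplitude > 0) {
      for (k in 1:3) {
        fr <- stats::runif(1, 0.2, 1) / max(h, w)   # period >= max dim
        fc <- stats::runif(1, 0.2, 1) / max(h, w)
        ph <- stats::runif(2, 0, 2 * pi)
        bg <- bg + (bgspec$amplitude / 3) *
          cos(2 * pi * fr * rr + ph[1]) * cos(2 * pi * fc * cc + ph[2])
      }
    }
    if (bgspec$n_blemishes > 0) {
      for (k in seq_len(bgspec$n_blemishes)) {
        br <- stats::runif(1, 1, h); bc <- stats::runif(1, 1, w)
        amp <- bgspec$blemish_amplitude * sample(c(-1, 1), 1)
        s2 <- 2 * bgspec$blemish_sigma^2
        bg <- bg + amp * exp(-((rr - br)^2 + (cc - bc)^2) / s2)
      }
    }
    bg
  })
}

## sample one cell's shape parameters from a phenotype model
sample_cell_params <- function(model) {
  r <- max(3, stats::rnorm(1, model$radius_px[1], model$radius_px[2]))
  e <- max(1, stats::rnorm(1, model$elongation[1], model$elongation[2]))
  p <- min(6, max(0.9, stats::rnorm(1, model$peak_phase_rad[1],
                                    model$peak_phase_rad[2])))
  theta <- stats::runif(1, 0, pi)
  list(radius = r, elongation = e, peak = p, theta = theta)
}

## render one dome onto a frame; returns the updated frame plus cell metadata
render_cell <- function(frame, cr, cc0, pars, profile) {
  a <- pars$radius * sqrt(pars$elongation)
  b <- pars$radius / sqrt(pars$elongation)
  ext <- if (profile == "gaussian") 3 * a else a
  r0 <- floor(cr - ext); r1 <- ceiling(cr + ext)
  c0 <- floor(cc0 - ext); c1 <- ceiling(cc0 + ext)
  border <- r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame)
  r0 <- max(1L, r0); r1 <- min(nrow(frame), r1)
  c0 <- max(1L, c0); c1 <- min(ncol(frame), c1)
  u <- matrix(r0:r1 - cr, r1 - r0 + 1, c1 - c0 + 1)
  v <- matrix(c0:c1 - cc0, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  ct <- cos(pars$theta); st <- sin(pars$theta)
  q <- ((u * ct + v * st) / a)^2 + ((-u * st + v * ct) / b)^2
  dome <- if (profile == "parabolic") pars$peak * pmax(0, 1 - q)
          else pars$peak * exp(-q / 2) * (q <= 9)
  frame[r0:r1, c0:c1] <- frame[r0:r1, c0:c1] + dome
  support <- matrix(FALSE, nrow(frame), ncol(frame))
  support[r0:r1, c0:c1] <- dome > 0
  list(frame = frame, volume = sum(dome), support = support, border = border)
}

#' Render a synthetic DHM acquisition with known ground truth
#'
#' Generates a stack of phase frames sharing one static background field
#' (the instrument's fixed optical path makes the background constant within
#' an acquisition), with cells drawn from the given phenotype models placed
#' at integer pixel centres under a minimum-separation constraint, plus
#' per-pixel Gaussian noise. Ground truth (label, centre, per-cell rendered
#' phase volume, support mask) is returned for every cell.
#'
#' @param spec a [scene_spec()].
#' @param models list of [phenotype_model()]; `count_fraction`s must sum to 1.
#' @param labels_by_frame optional list (length `n_frames`) of character
#'   vectors fixing each frame's cell labels exactly; overrides
#'   `count_fraction` sampling and `cells_per_frame`. Used by
#'   [render_spike_in()] for deterministic class allocation.
#' @return an object of class `dhm_scene`: `frames` (list of matrices, rad),
#'   `background` (matrix), `truth` (data frame: `frame_id`, `cell_id`,
#'   `label`, `center_row`, `center_col`, `radius_px`, `elongation`,
#'   `peak_phase_rad`, `volume_rad_px`, `border`), `masks` (per-cell
#'   run-length-encoded support masks), and `spec`.
#' @export
#' @examples
#' sc <- render_scene(scene_spec(frame_shape = c(128, 160), n_frames = 2,
#'                               cells_per_frame = 3, seed = 7),
#'                    default_phenotype_models())
#' sc$truth[, c("frame_id", "label", "center_row", "center_col")]
render_scene <- function(spec, models, labels_by_frame = NULL) {
  stopifnot(inherits(spec, "scene_spec"), length(models) >= 1)
  for (m in models) stopifnot(inherits(m, "phenotype_model"))
  fr <- vapply(models, `[[`, numeric(1), "count_fraction")
  if (is.null(labels_by_frame) && abs(sum(fr) - 1) > 1e-8)
    stop("count_fraction values over all models must sum to 1 (got ",
         format(sum(fr)), ")")
  names(models) <- vapply(models, `[[`, character(1), "name")
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  if (!is.null(labels_by_frame)) stopifnot(length(labels_by_frame) == spec$n_frames)

  background <- make_background(spec)
  frames <- vector("list", spec$n_frames)
  truth <- list(); masks <- list()

  with_seed(derive_seed(spec$seed, "cells"), {
    for (f in seq_len(spec$n_frames)) {
      frame <- background
      labs <- if (is.null(labels_by_frame)) {
        if (spec$cells_per_frame > 0)
          sample(names(models), spec$cells_per_frame, replace = TRUE, prob = fr)
        else character(0)
      } else labels_by_frame[[f]]
      centers <- matrix(numeric(0), 0, 2)
      lo_r <- spec$margin_px + 1; hi_r <- h - spec$margin_px
      lo_c <- spec$margin_px + 1; hi_c <- w - spec$margin_px
      if (length(labs) > 0 && (lo_r > hi_r || lo_c > hi_c))
        stop("frame ", f, " too small to place cells with margin ",
             spec$margin_px)
      for (i in seq_along(labs)) {
        placed <- FALSE
        for (try in seq_len(2000L)) {
          cr <- sample(lo_r:hi_r, 1); cc0 <- sample(lo_c:hi_c, 1)
          if (nrow(centers) == 0 ||
              min((centers[, 1] - cr)^2 + (centers[, 2] - cc0)^2) >=
                spec$min_separation_px^2) {
            placed <- TRUE; break
          }
        }
        if (!placed)
          stop("could not place cell ", i, " in frame ", f,
               " at min_separation ", spec$min_separation_px, " px")
        centers <- rbind(centers, c(cr, cc0))
        pars <- sample_cell_params(models[[labs[i]]])
        rc <- render_cell(frame, cr, cc0, pars, models[[labs[i]]]$profile)
        frame <- rc$frame
        truth[[length(truth) + 1L]] <- data.frame(
          frame_id = f, cell_id = i, label = labs[i],
          center_row = cr, center_col = cc0,
          radius_px = pars$radius, elongation = pars$elongation,
          peak_phase_rad = pars$peak, volume_rad_px = rc$volume,
          border = rc$border)
        masks[[length(masks) + 1L]] <- encode_mask_rle(rc$support)
      }
      if (spec$noise_sd_rad > 0)
        frame <- frame + matrix(stats::rnorm(h * w, 0, spec$noise_sd_rad), h, w)
      if (!all(is.finite(frame))) stop("non-finite phase values in frame ", f)
      frames[[f]] <- frame
    }
  })

  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(frame_id = integer(0), cell_id = integer(0),
                           label = character(0), center_row = integer(0),
                           center_col = integer(0), radius_px = numeric(0),
                           elongation = numeric(0), peak_phase_rad = numeric(0),
                           volume_rad_px = numeric(0), border = logical(0))
  structure(list(frames = frames, background = background, truth = truth,
                 masks = masks, spec = spec, models = models),
            class = "dhm_scene")
}

#' @export
print.dhm_scene <- function(x, ...) {
  cat("<dhm_scene>", length(x$frames), "frame(s) of",
      paste(x$spec$frame_shape, collapse = " x "), "px,",
      nrow(x$truth), "cells\n")
  if (nrow(x$truth)) print(table(x$truth$label))
  invisible(x)
}

#' Render a deterministic two-population spike-in scene
#'
#' Emulates a spike-in experiment in which a characterized epithelial and a
#' characterized mesenchymal line are mixed in a defined ratio. Class counts
#' are allocated deterministically -- exactly `round(p_mesenchymal * n_cells)`
#' mesenchymal cells (R's `round()`, round-half-even) -- rather than sampled,
#' so mixture-recovery experiments have exact ground truth.
#'
#' @param p_mesenchymal true mesenchymal fraction in `[0, 1]`.
#' @param n_cells total number of cells.
#' @param seed integer seed.
#' @param models list of two [phenotype_model()]s, one of which must be named
#'   `"mesenchymal"`; defaults to [default_phenotype_models()].
#' @param cells_per_frame,frame_shape,noise_sd_rad forwarded to [scene_spec()].
#' @return a `dhm_scene` whose truth table contains exactly
#'   `round(p_mesenchymal * n_cells)` mesenchymal cells.
#' @export
render_spike_in <- function(p_mesenchymal, n_cells, seed,
                            models = default_phenotype_models(),
                            cells_per_frame = 12L,
                            frame_shape = c(384L, 512L),
                            noise_sd_rad = 0.05) {
  stopifnot(p_mesenchymal >= 0, p_mesenchymal <= 1, n_cells >= 0)
  nm <- vapply(models, `[[`, character(1), "name")
  if (!"mesenchymal" %in% nm)
    stop("spike-in models must include one named 'mesenchymal'")
  n_mes <- round(p_mesenchymal * n_cells)
  labs <- c(rep("mesenchymal", n_mes), rep(nm[nm != "mesenchymal"][1], n_cells - n_mes))
  labs <- with_seed(derive_seed(seed, "spikein-shuffle"),
                    sample(labs, length(labs)))
  n_frames <- max(1L, ceiling(n_cells / cells_per_frame))
  by_frame <- split(labs, rep(seq_len(n_frames),
                              each = cells_per_frame)[seq_along(labs)])
  lbf <- vector("list", n_frames)
  for (f in seq_len(n_frames)) lbf[[f]] <- by_frame[[as.character(f)]] %||% character(0)
  spec <- scene_spec(frame_shape = frame_shape, n_frames = n_frames,
                     cells_per_frame = cells_per_frame,
                     noise_sd_rad = noise_sd_rad, seed = seed)
  render_scene(spec, models, labels_by_frame = lbf)
}
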