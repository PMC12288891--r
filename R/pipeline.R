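#' Default end-to-end run configuration
#'
#' A run configuration is a plain nested list (round-trippable to YAML with
#' [read_config()] / [write_config()]) with these blocks:
#'
#' * `seed`: global integer seed; every stage derives its own seed from it
#'   via [derive_seed()] (documented hash), so stages are independently
#'   reproducible.
#' * `simulate`: either `kind = "spike_in"` with `p_mesenchymal`, `n_cells`,
#'   or `kind = "scene"` with `n_frames`, `cells_per_frame`,
#'   `p_mesenchymal`, `include_hybrid`; plus shared `frame_shape`,
#'   `noise_sd_rad`. Set `enabled = FALSE` and give `input$frames` (a TIFF
#'   written by [write_frames()]) plus optional `input$truth` to ingest real
#'   data instead.
#' * `preprocess`: `background_n` (50), `threshold` (0.8 rad), `min_area`
#'   (30 px), `patch_px` (96).
#' * `features`: `version` ("v1"), optional `bounds` (named list of
#'   `c(lower, upper)`), `deep` (`enabled`, FALSE by default).
#' * `classify`: `enabled`, `methods` (default `"random_forest"`),
#'   `folds` (5), `balance` (TRUE).
#' * `embed`: `enabled`, `n_neighbors` (15), `min_dist` (0.1).
#' * `write_images`: write the simulated frames as TIFF.
#'
#' @return the default configuration list.
#' @export
default_config <- function() {
  list(seed = 1L,
       simulate = list(enabled = TRUE, kind = "spike_in",
                       p_mesenchymal = 0.5, n_cells = 200L,
                       n_frames = 10L, cells_per_frame = 12L,
                       frame_shape = c(384L, 512L), noise_sd_rad = 0.05,
                       include_hybrid = FALSE),
       input = list(frames = NULL, truth = NULL),
       preprocess = list(background_n = 50L, threshold = 0.8,
                         min_area = 30L, patch_px = 96L),
       features = list(version = "v1", bounds = NULL,
                       deep = list(enabled = FALSE)),
       classify = list(enabled = TRUE, methods = "random_forest",
                       folds = 5L, balance = TRUE),
       embed = list(enabled = TRUE, n_neighbors = 15, min_dist = 0.1),
       write_images = FALSE)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()`: the configuration merged over [default_config()].
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the end-to-end phenotyping pipeline
#'
#' Executes simulate/ingest, preprocessing, feature extraction, optional
#' deep embedding, classification and embedding/heterogeneity scoring from a
#' single configuration, writing all stage artifacts plus a machine-readable
#' manifest. Re-running with the same configuration reproduces all numeric
#' outputs byte-identically.
#'
#' Artifacts written to `out_dir`: `features.csv`, `patches_index.csv`,
#' `truth.csv` (simulation only), per-method `cv_<method>.json`,
#' `embedding.csv`, `heterogeneity.csv`, `summary.json`, `manifest.json`,
#' and (if configured) `frames.tif`.
#'
#' @param config configuration list (see [default_config()]) or a YAML path.
#' @param out_dir output directory, created if needed.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  stopifnot(is.numeric(config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "dhmpheno",
                   version = as.character(utils::packageVersion("dhmpheno")),
                   seed = config$seed, stages = list(), counts = list())
  fail <- function(stage, msg) stop("stage '", stage, "' failed: ", msg,
                                    call. = FALSE)

  ## ---- stage 1: simulate or ingest ----
  truth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sseed <- derive_seed(config$seed, "simulate")
    manifest$stages$simulate <- list(seed = sseed)
    sim <- config$simulate
    scene <- tryCatch({
      if (identical(sim$kind, "spike_in")) {
        render_spike_in(sim$p_mesenchymal, sim$n_cells, seed = sseed,
                        cells_per_frame = sim$cells_per_frame,
                        frame_shape = unlist(sim$frame_shape),
                        noise_sd_rad = sim$noise_sd_rad)
      } else {
        render_scene(scene_spec(frame_shape = unlist(sim$frame_shape),
                                n_frames = sim$n_frames,
                                cells_per_frame = sim$cells_per_frame,
                                noise_sd_rad = sim$noise_sd_rad,
                                seed = sseed),
                     default_phenotype_models(sim$p_mesenchymal %||% 0.5,
                                              isTRUE(sim$include_hybrid)))
      }
    }, error = function(e) fail("simulate", conditionMessage(e)))
    frames <- scene$frames
    truth <- scene$truth
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    if (isTRUE(config$write_images))
      write_frames(frames, file.path(out_dir, "frames.tif"))
  } else {
    if (is.null(config$input$frames)) fail("ingest", "no input frames given")
    frames <- tryCatch(read_frames(config$input$frames),
                       error = function(e) fail("ingest", conditionMessage(e)))
    if (!is.null(config$input$truth))
      truth <- utils::read.csv(config$input$truth)
  }
  manifest$counts$frames <- length(frames)
  manifest$counts$true_cells <- if (is.null(truth)) NA_integer_ else nrow(truth)

  ## ---- stage 2: preprocess ----
  pp <- tryCatch(
    preprocess_stack(frames,
                     background_n = config$preprocess$background_n,
                     threshold = config$preprocess$threshold,
                     min_area = config$preprocess$min_area,
                     patch_px = config$preprocess$patch_px),
    error = function(e) fail("preprocess", conditionMessage(e)))
  manifest$counts$contours_detected <- unname(pp$counts[["n_contours"]])
  manifest$counts$area_survivors <- unname(pp$counts[["n_contours"]] -
                                             pp$counts[["rejected_small"]])
  manifest$counts$border_rejections <- unname(pp$counts[["rejected_border"]])
  manifest$counts$cells_kept <- unname(pp$counts[["kept"]])
  utils::write.csv(pp$index, file.path(out_dir, "patches_index.csv"),
                   row.names = FALSE)

  ## ---- stage 3: morphology features (+ optional bounds) ----
  feats <- tryCatch(compute_features(pp, version = config$features$version),
                    error = function(e) fail("features", conditionMessage(e)))
  if (!is.null(config$features$bounds) && length(config$features$bounds)) {
    b <- do.call(feature_bounds, lapply(config$features$bounds, unlist))
    fb <- apply_feature_bounds(feats, b)
    manifest$counts$bounds_rejections <- fb$n_rejected
    feats <- fb$kept
  } else manifest$counts$bounds_rejections <- 0L

  ## ---- stage 4: deep embedding channel ----
  if (isTRUE(config$features$deep$enabled)) {
    dseed <- derive_seed(config$seed, "deep")
    manifest$stages$deep <- list(seed = dseed,
                                 weights_source = "seeded-random")
    kept_rows <- match(paste(feats$frame_id, feats$cell_id),
                       paste(pp$index$frame_id, pp$index$cell_id))
    emb <- tryCatch(
      embed_patches(pp$patches[kept_rows], embedding_spec(seed = dseed)),
      error = function(e) fail("deep", conditionMessage(e)))
    feats <- cbind(feats, as.data.frame(emb))
  }
  utils::write.csv(feats, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  ## attach labels for supervised stages (simulated runs: via truth matching)
  labels <- NULL
  if (!is.null(truth) && nrow(feats)) {
    matched <- match_to_truth(
      data.frame(frame_id = feats$frame_id,
                 centroid_row = pp$index$centroid_row[
                   match(paste(feats$frame_id, feats$cell_id),
                         paste(pp$index$frame_id, pp$index$cell_id))],
                 centroid_col = pp$index$centroid_col[
                   match(paste(feats$frame_id, feats$cell_id),
                         paste(pp$index$frame_id, pp$index$cell_id))]),
      truth)
    labels <- matched$label
  }

  ## ---- stage 5: classification ----
  feature_cols <- setdiff(names(feats),
                          c("frame_id", "cell_id", "qc_pass"))
  if (isTRUE(config$classify$enabled) && !is.null(labels) &&
      length(unique(stats::na.omit(labels))) >= 2) {
    ok <- !is.na(labels) & feats$qc_pass
    x <- feats[ok, feature_cols, drop = FALSE]
    y <- labels[ok]
    cseed <- derive_seed(config$seed, "classify")
    if (isTRUE(config$classify$balance)) {
      bal <- balance_classes(x, y, seed = cseed)
      x <- bal$features; y <- bal$labels
    }
    manifest$counts$cells_classified <- length(y)
    manifest$stages$classify <- list(seed = cseed)
    for (m in config$classify$methods) {
      rep <- tryCatch(
        cross_validate(x, y, method = m, folds = config$classify$folds,
                       seed = cseed),
        error = function(e) fail("classify", conditionMessage(e)))
      jsonlite::write_json(
        list(method = rep$method, seed = rep$seed,
             fold_accuracies = rep$fold_accuracies,
             median = rep$median, quartiles = as.list(rep$quartiles),
             classes = rep$classes,
             confusion = as.data.frame(rep$confusion)),
        file.path(out_dir, paste0("cv_", rep$method, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  } else manifest$counts$cells_classified <- 0L

  ## ---- stage 6: embedding + heterogeneity ----
  if (isTRUE(config$embed$enabled) && !is.null(labels) &&
      sum(!is.na(labels) & feats$qc_pass) >= 10) {
    ok <- !is.na(labels) & feats$qc_pass
    eseed <- derive_seed(config$seed, "embed")
    manifest$stages$embed <- list(seed = eseed)
    emb <- tryCatch(
      embed_cells(feats[ok, feature_cols, drop = FALSE], labels[ok],
                  n_neighbors = config$embed$n_neighbors,
                  min_dist = config$embed$min_dist, seed = eseed),
      error = function(e) fail("embed", conditionMessage(e)))
    utils::write.csv(
      data.frame(frame_id = feats$frame_id[ok], cell_id = feats$cell_id[ok],
                 UMAP1 = emb$coords[, 1], UMAP2 = emb$coords[, 2],
                 sample = as.character(emb$sample)),
      file.path(out_dir, "embedding.csv"), row.names = FALSE)
    het <- heterogeneity_score(emb)
    utils::write.csv(
      data.frame(frame_id = feats$frame_id[ok], cell_id = feats$cell_id[ok],
                 sample = as.character(het$per_cell$sample),
                 d = het$per_cell$d),
      file.path(out_dir, "heterogeneity.csv"), row.names = FALSE)
    summ <- list(per_sample_mean = as.list(het$per_sample_mean))
    if (nlevels(het$per_cell$sample) >= 2) {
      ht <- compare_heterogeneity(het)
      summ$test <- list(method = ht$method, statistic = ht$statistic,
                        p.value = ht$p.value)
      if (!is.null(ht$pairwise)) summ$test$pairwise <- ht$pairwise
    }
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
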