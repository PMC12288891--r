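#' Jointly embed all cells of a comparison with UMAP
#'
#' All samples of one comparison are z-scored and embedded together in a
#' single 2D UMAP fit, so that coordinates -- and therefore heterogeneity
#' scores -- are comparable across samples within that fit. UMAP coordinates
#' have arbitrary scale; scores must never be compared across different
#' embeddings.
#'
#' @param features numeric feature matrix or data frame (provenance columns
#'   dropped automatically).
#' @param sample per-cell sample label (cell line / organoid line /
#'   condition).
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1).
#' @param seed integer seed; the same seed reproduces coordinates exactly.
#' @return object of class `dhm_embedding`: `coords` (n x 2, columns
#'   `UMAP1`, `UMAP2`), `sample` (factor), `params`, `n`.
#' @export
embed_cells <- function(features, sample, n_neighbors = 15, min_dist = 0.1,
                        seed = 1L) {
  x <- as_feature_matrix(features)
  if (nrow(x) < 10) stop("need at least 10 cells to embed, got ", nrow(x))
  bad <- which(!apply(x, 1, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite features for cell row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  sample <- factor(as.character(sample))
  stopifnot(length(sample) == nrow(x))
  x <- zscore_apply(x, zscore_fit(x))
  coords <- with_seed(seed, {
    uwot::umap(x, n_neighbors = min(n_neighbors, nrow(x) - 1),
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  })
  colnames(coords) <- c("UMAP1", "UMAP2")
  structure(list(coords = coords, sample = sample,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, seed = seed),
                 n = nrow(coords)),
            class = "dhm_embedding")
}

#' @export
print.dhm_embedding <- function(x, ...) {
  cat("<dhm_embedding>", x$n, "cells,", nlevels(x$sample), "sample(s);",
      "n_neighbors =", x$params$n_neighbors,
      "min_dist =", x$params$min_dist, "\n")
  invisible(x)
}

#' @export
plot.dhm_embedding <- function(x, contours = TRUE, ...) {
  cols <- grDevices::hcl.colors(max(3, nlevels(x$sample)), "Dark 3")
  graphics::plot(x$coords, col = cols[as.integer(x$sample)], pch = 16,
                 cex = 0.6, ...)
  if (contours) {
    cl <- try(density_contours(x$coords, x$sample), silent = TRUE)
    if (!inherits(cl, "try-error") && nrow(cl))
      for (key in unique(paste(cl$group, cl$level, cl$piece))) {
        seg <- cl[paste(cl$group, cl$level, cl$piece) == key, ]
        graphics::lines(seg$x, seg$y,
                        col = cols[as.integer(factor(seg$group[1],
                                                     levels(x$sample)))])
      }
  }
  graphics::legend("topright", legend = levels(x$sample),
                   col = cols[seq_len(nlevels(x$sample))], pch = 16, cex = 0.8)
  invisible(x)
}

#' Per-group kernel-density contour lines in an embedding
#'
#' Bivariate Gaussian kernel density estimation (normal-reference bandwidth)
#' per group on a common regular grid; contour levels are
#' highest-density-region quantiles, i.e. `levels = 0.5` traces the contour
#' enclosing 50% of a group's probability mass.
#'
#' @param coords n x 2 coordinate matrix.
#' @param groups per-point group label.
#' @param grid_n grid resolution per axis (default 100).
#' @param levels probability-mass quantiles for the contours.
#' @return data frame of polylines: `group`, `level`, `piece`, `x`, `y`,
#'   with attribute `grid_mass` (per-group KDE mass on the grid, ~1).
#' @export
density_contours <- function(coords, groups, grid_n = 100,
                             levels = c(0.25, 0.5, 0.75)) {
  coords <- as.matrix(coords)
  groups <- factor(as.character(groups))
  stopifnot(nrow(coords) == length(groups), ncol(coords) == 2)
  pad <- 0.1 * c(diff(range(coords[, 1])), diff(range(coords[, 2])))
  lims <- c(range(coords[, 1]) + c(-1, 1) * pad[1],
            range(coords[, 2]) + c(-1, 1) * pad[2])
  out <- list(); mass <- c()
  for (g in levels(groups)) {
    i <- groups == g
    if (sum(i) < 5) { warning("group '", g, "' has fewer than 5 points; skipped"); next }
    if (stats::sd(coords[i, 1]) < 1e-12 || stats::sd(coords[i, 2]) < 1e-12) {
      warning("group '", g, "' is degenerate (coincident points); skipped")
      next
    }
    kd <- MASS::kde2d(coords[i, 1], coords[i, 2], n = grid_n, lims = lims)
    cellarea <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    mass[g] <- sum(kd$z) * cellarea
    dens <- sort(as.vector(kd$z), decreasing = TRUE)
    cum <- cumsum(dens) * cellarea / mass[g]
    thr <- vapply(levels, function(p) dens[which(cum >= p)[1]], numeric(1))
    for (li in seq_along(levels)) {
      cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = thr[li])
      for (pi in seq_along(cl))
        out[[length(out) + 1L]] <- data.frame(
          group = g, level = levels[li], piece = pi,
          x = cl[[pi]]$x, y = cl[[pi]]$y)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(group = character(0), level = numeric(0),
                         piece = integer(0), x = numeric(0), y = numeric(0))
  attr(res, "grid_mass") <- mass
  res
}

#' Select the most important features by random-forest importance
#'
#' Fits a random forest over the comparison's labels and ranks features by
#' impurity-based (mean decrease in Gini) importance, descending, ties broken
#' by feature name for stability.
#'
#' @param features numeric feature matrix or data frame.
#' @param labels per-cell label of the comparison.
#' @param k number of features to return (default 26).
#' @param seed integer seed for the forest.
#' @return character vector of `k` feature names, most important first.
#' @export
select_top_features <- function(features, labels, k = 26L, seed = 1L) {
  x <- as_feature_matrix(features)
  if (k > ncol(x))
    stop("k = ", k, " exceeds the ", ncol(x), " available features")
  y <- factor(as.character(labels))
  rf <- with_seed(seed, randomForest::randomForest(x, y, ntree = 100))
  imp <- randomForest::importance(rf)[, 1]
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(k)]
}

#' Single-linkage dendrogram over sample representatives
#'
#' Each sample is represented by the per-feature median of its cells over
#' the selected (z-scored) features; samples are clustered by single-linkage
#' agglomeration on Euclidean distances. Single-linkage merge heights equal
#' the minimum-spanning-tree edge weights of the representative distance
#' graph.
#'
#' @param features numeric feature matrix or data frame (all cells).
#' @param sample_labels per-cell sample label (>= 2 samples, none empty).
#' @param top_features feature names to use (e.g. from
#'   [select_top_features()]); `NULL` uses all columns.
#' @return object of class `dhm_dendrogram`: `hclust`, `heights`,
#'   `leaf_labels`, `features`, `representatives` (samples x features).
#' @export
sample_dendrogram <- function(features, sample_labels, top_features = NULL) {
  x <- as_feature_matrix(features)
  if (!is.factor(sample_labels)) sample_labels <- factor(sample_labels)
  stopifnot(nrow(x) == length(sample_labels))
  if (nlevels(sample_labels) < 2) stop("need at least 2 samples")
  empty <- levels(sample_labels)[table(sample_labels) == 0]
  if (length(empty)) stop("sample with 0 cells: ", empty[1])
  x <- zscore_apply(x, zscore_fit(x))
  if (!is.null(top_features)) {
    missing <- setdiff(top_features, colnames(x))
    if (length(missing)) stop("unknown feature(s): ",
                              paste(missing, collapse = ", "))
    x <- x[, top_features, drop = FALSE]
  }
  reps <- t(vapply(levels(sample_labels), function(s)
    apply(x[sample_labels == s, , drop = FALSE], 2, stats::median),
    numeric(ncol(x))))
  hc <- stats::hclust(stats::dist(reps), method = "single")
  structure(list(hclust = hc, heights = hc$height,
                 leaf_labels = levels(sample_labels),
                 features = colnames(x), representatives = reps),
            class = "dhm_dendrogram")
}

#' @export
print.dhm_dendrogram <- function(x, ...) {
  cat("<dhm_dendrogram>", length(x$leaf_labels), "samples on",
      length(x$features), "features; merge heights:",
      paste(sprintf("%.3f", x$heights), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.dhm_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}

#' Export a sample dendrogram in Newick format
#'
#' @param dendro a `dhm_dendrogram`.
#' @param path output file; `NULL` returns the Newick string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "dhm_dendrogram"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  phy <- ape::as.phylo(dendro$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Tumor heterogeneity score in the joint embedding
#'
#' For every cell `i` of a sample, the score is the squared Euclidean
#' distance `d_i = || x_i - c ||^2` of its 2D embedding coordinates to the
#' sample's centroid `c` (the mean coordinate of that sample's cells); the
#' per-sample mean of `d_i` is the sample's heterogeneity score (the Ø
#' score). Here "cluster" means the labelled sample, not an unsupervised
#' cluster. Scores are comparable only within one fitted embedding.
#'
#' @param embedding a `dhm_embedding`, or an n x 2 coordinate matrix (then
#'   `sample` is required).
#' @param sample per-cell sample labels when `embedding` is a matrix.
#' @return object of class `dhm_heterogeneity`: `per_cell` (data frame
#'   `sample`, `d`), `per_sample_mean` (named, the Ø scores), `centroids`,
#'   `space = "embedding-2d"`.
#' @export
heterogeneity_score <- function(embedding, sample = NULL) {
  if (inherits(embedding, "dhm_embedding")) {
    coords <- embedding$coords; sample <- embedding$sample
  } else {
    coords <- as.matrix(embedding)
    if (is.null(sample)) stop("sample labels required with raw coordinates")
    sample <- factor(as.character(sample))
  }
  stopifnot(ncol(coords) == 2, nrow(coords) == length(sample))
  sample <- droplevels(sample)
  d <- numeric(nrow(coords))
  centroids <- matrix(NA_real_, nlevels(sample), 2,
                      dimnames = list(levels(sample), c("x", "y")))
  for (s in levels(sample)) {
    i <- sample == s
    if (sum(i) == 1) {
      warning("sample '", s, "' has a single cell; its score is 0 (degenerate)")
      centroids[s, ] <- coords[i, ]
      d[i] <- 0
      next
    }
    c0 <- colMeans(coords[i, , drop = FALSE])
    centroids[s, ] <- c0
    d[i] <- (coords[i, 1] - c0[1])^2 + (coords[i, 2] - c0[2])^2
  }
  structure(list(per_cell = data.frame(sample = sample, d = d),
                 per_sample_mean = vapply(levels(sample), function(s)
                   mean(d[sample == s]), numeric(1)),
                 centroids = centroids, space = "embedding-2d"),
            class = "dhm_heterogeneity")
}

#' @export
print.dhm_heterogeneity <- function(x, ...) {
  cat("<dhm_heterogeneity> mean score (Ø) per sample:\n")
  print(round(x$per_sample_mean, 4))
  invisible(x)
}

#' Dunn's multiple-comparisons test
#'
#' Rank-based post hoc test following a Kruskal-Wallis test: pairwise z
#' statistics on mean ranks with the tie correction, two-sided p values,
#' adjusted across all pairs (Bonferroni by default).
#'
#' @param x numeric values.
#' @param g group label per value (>= 2 groups).
#' @param p.adjust.method adjustment passed to [stats::p.adjust()].
#' @return data frame: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g, p.adjust.method = "bonferroni") {
  g <- factor(as.character(g))
  stopifnot(length(x) == length(g), nlevels(g) >= 2)
  if (any(table(g) == 0)) stop("empty group: ",
                               levels(g)[table(g) == 0][1])
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / n[a] + 1 / n[b]))
    z[k] <- (rbar[a] - rbar[b]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = pmin(1, stats::p.adjust(p, method = p.adjust.method)))
}

#' Compare heterogeneity scores between samples
#'
#' Two samples are compared with a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test; more than two with a Kruskal-Wallis test followed by
#' Dunn's post hoc test (Bonferroni-adjusted across pairs). The normal
#' approximation without continuity correction is used for the Mann-Whitney
#' test, so two groups that are permutations of each other give p = 1.
#'
#' @param het a `dhm_heterogeneity`, or a numeric vector of scores (then
#'   `groups` is required).
#' @param groups group label per score when `het` is a vector.
#' @param p.adjust.method adjustment for Dunn's pairwise p values.
#' @return object of class `dhm_het_test`: `method`, `statistic`, `p.value`,
#'   `pairwise` (Dunn table, or NULL for two groups), `group_means`.
#' @export
compare_heterogeneity <- function(het, groups = NULL,
                                  p.adjust.method = "bonferroni") {
  if (inherits(het, "dhm_heterogeneity")) {
    x <- het$per_cell$d; g <- het$per_cell$sample
  } else {
    x <- as.numeric(het)
    if (is.null(groups)) stop("groups required with raw scores")
    g <- factor(as.character(groups))
  }
  g <- droplevels(factor(g))
  if (any(table(g) == 0) || nlevels(g) < 2)
    stop("need at least 2 non-empty groups")
  gm <- tapply(x, g, mean)
  if (nlevels(g) == 2) {
    i <- g == levels(g)[1]
    wt <- suppressWarnings(stats::wilcox.test(x[i], x[!i],
                                              alternative = "two.sided",
                                              exact = FALSE, correct = FALSE))
    res <- list(method = "mann-whitney", statistic = unname(wt$statistic),
                p.value = wt$p.value, pairwise = NULL, group_means = gm)
  } else {
    kw <- stats::kruskal.test(x, g)
    res <- list(method = "kruskal-wallis",
                statistic = unname(kw$statistic), df = unname(kw$parameter),
                p.value = kw$p.value,
                pairwise = dunn_test(x, g, p.adjust.method),
                group_means = gm)
  }
  structure(res, class = "dhm_het_test")
}

#' @export
print.dhm_het_test <- function(x, ...) {
  cat("<dhm_het_test>", x$method, "| statistic =",
      sprintf("%.3f", x$statistic), "| p =", format.pval(x$p.value), "\n")
  if (!is.null(x$pairwise)) {
    cat("  Dunn's post hoc (adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
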