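#' Specify the convolutional embedding channel
#'
#' Complements the morphology bank with a learned-style embedding from an
#' 18-convolutional-layer residual network (ResNet18 topology: 7x7 stem,
#' max-pool, four stages of two residual blocks at 64/128/256/512 channels,
#' global average pooling; classification head removed). Only
#' `weights_source = "seeded-random"` is available in this package: weights
#' are drawn once from `seed` (He-scaled Gaussians), making the channel fully
#' reproducible and self-contained; no learned weights are shipped or
#' downloaded. Requesting `"pretrained-natural-images"` raises an error
#' directing the user to the seeded mode.
#'
#' @param backbone architecture id; only `"resnet18"` is implemented.
#' @param weights_source `"seeded-random"` or `"pretrained-natural-images"`.
#' @param embed_dim embedding width; the resnet18 backbone yields 512.
#' @param seed integer seed for weight generation.
#' @param input_range phase range affinely mapped to `[0, 1]` at the input;
#'   default `c(-2, 6)` rad, the interval DHM phase images typically occupy.
#' @return object of class `embedding_spec`.
#' @export
embedding_spec <- function(backbone = "resnet18",
                           weights_source = c("seeded-random",
                                              "pretrained-natural-images"),
                           embed_dim = 512L, seed = 1L,
                           input_range = c(-2, 6)) {
  weights_source <- match.arg(weights_source)
  if (!identical(backbone, "resnet18"))
    stop("unknown backbone: ", backbone)
  if (embed_dim != 512L)
    stop("the resnet18 backbone yields a 512-d embedding; got embed_dim = ",
         embed_dim)
  structure(list(backbone = backbone, weights_source = weights_source,
                 embed_dim = as.integer(embed_dim), seed = as.integer(seed),
                 input_range = input_range),
            class = "embedding_spec")
}

## --- minimal conv-net machinery on (h*w x channels) column-major maps -----

## linear indices into a zero-padded (hp x wp) plane for every output
## position (rows) and kernel offset (cols); reused across channels/patches
im2col_indices <- function(h, w, k, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  r0 <- rep(seq(1L, by = stride, length.out = ho), times = wo)
  c0 <- rep(seq(1L, by = stride, length.out = wo), each = ho)
  off_r <- rep(0:(k - 1L), times = k)
  off_c <- rep(0:(k - 1L), each = k)
  idx <- outer(seq_len(ho * wo), seq_len(k * k),
               function(i, j) (c0[i] + off_c[j] - 1L) * hp + r0[i] + off_r[j])
  list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
}

pad_map <- function(x, h, w, pad) {
  if (pad == 0L) return(x)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  out <- matrix(0, hp * wp, ncol(x))
  rows <- rep(pad + seq_len(h), times = w)
  cols <- rep(pad + seq_len(w), each = h)
  out[(cols - 1L) * hp + rows, ] <- x
  out
}

## x: (h*w x Cin) map -> (ho*wo x k*k*Cin) patches -> %*% weights
conv_forward <- function(x, h, w, weights, k, stride, pad, geom) {
  xp <- pad_map(x, h, w, pad)
  cin <- ncol(x)
  A <- xp[as.vector(geom$idx), , drop = FALSE]       # (ho*wo*k2) x Cin
  dim(A) <- NULL
  A <- matrix(A, nrow = geom$ho * geom$wo)           # (ho*wo) x (k2*Cin)
  A %*% weights
}

maxpool_forward <- function(x, h, w, k, stride, pad, geom) {
  xp <- pad_map(x, h, w, pad)
  n <- geom$ho * geom$wo
  out <- matrix(-Inf, n, ncol(x))
  for (j in seq_len(k * k))
    out <- pmax(out, xp[geom$idx[, j], , drop = FALSE])
  out
}

## network definition: list of layers with geometry resolved for the input
build_resnet18 <- function(spec, h, w) {
  he <- function(k, cin, cout)
    matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
           k * k * cin, cout)
  stages <- list(c(64L, 1L), c(64L, 1L), c(128L, 2L), c(256L, 2L), c(512L, 2L))
  with_seed(spec$seed, {
    net <- list()
    geom_cache <- new.env()
    geom <- function(h, w, k, s, p) {
      key <- paste(h, w, k, s, p, sep = "_")
      if (is.null(geom_cache[[key]]))
        geom_cache[[key]] <- im2col_indices(h, w, k, s, p)
      geom_cache[[key]]
    }
    ## stem: conv 7x7/2 + maxpool 3x3/2
    g <- geom(h, w, 7L, 2L, 3L)
    net$stem <- list(w = he(7L, 3L, 64L), k = 7L, s = 2L, p = 3L,
                     h = h, w_ = w, geom = g)
    h <- g$ho; w <- g$wo
    g <- geom(h, w, 3L, 2L, 1L)
    net$pool <- list(k = 3L, s = 2L, p = 1L, h = h, w_ = w, geom = g)
    h <- g$ho; w <- g$wo
    cin <- 64L
    net$blocks <- list()
    for (st in 2:5) {
      cout <- stages[[st]][1]; s1 <- stages[[st]][2]
      for (b in 1:2) {
        s <- if (b == 1) s1 else 1L
        g1 <- geom(h, w, 3L, s, 1L)
        g2 <- geom(g1$ho, g1$wo, 3L, 1L, 1L)
        blk <- list(w1 = he(3L, cin, cout), w2 = he(3L, cout, cout),
                    s = s, h = h, w_ = w, g1 = g1, g2 = g2,
                    proj = if (s != 1L || cin != cout) {
                      gs <- geom(h, w, 1L, s, 0L)
                      list(w = he(1L, cin, cout), geom = gs)
                    })
        net$blocks[[length(net$blocks) + 1L]] <- blk
        h <- g1$ho; w <- g1$wo
        cin <- cout
      }
    }
    net$out_hw <- c(h, w)
    net
  })
}

resnet18_forward <- function(net, x) {   # x: (h*w x 3) in [0,1]
  st <- net$stem
  x <- conv_forward(x, st$h, st$w_, st$w, st$k, st$s, st$p, st$geom)
  x <- pmax(x, 0)
  pl <- net$pool
  x <- maxpool_forward(x, pl$h, pl$w_, pl$k, pl$s, pl$p, pl$geom)
  for (blk in net$blocks) {
    y <- conv_forward(x, blk$h, blk$w_, blk$w1, 3L, blk$s, 1L, blk$g1)
    y <- pmax(y, 0)
    y <- conv_forward(y, blk$g1$ho, blk$g1$wo, blk$w2, 3L, 1L, 1L, blk$g2)
    skip <- if (is.null(blk$proj)) x
            else conv_forward(x, blk$h, blk$w_, blk$proj$w, 1L, blk$s, 0L,
                              blk$proj$geom)
    x <- pmax((y + skip) / sqrt(2), 0)   # /sqrt(2) keeps variance stable
  }
  colMeans(x)                            # global average pool -> 512
}

#' Embed cell patches with the convolutional backbone
#'
#' Each single-channel phase patch is affinely mapped from
#' `spec$input_range` to `[0, 1]`, replicated to 3 channels, and passed
#' through the backbone; the global-average-pooled 512-d activation is the
#' embedding. Deterministic for a fixed `spec` (weights are a pure function
#' of `spec$seed`). Patches are fed at their native size (no resizing): the
#' backbone is fully convolutional down to the pooling stage.
#'
#' @param patches a `dhm_patches` collection, a list of `cell_patch`
#'   objects, or a list of equally sized numeric matrices.
#' @param spec an [embedding_spec()].
#' @return numeric matrix, one row per patch, columns `deep_001` ...
#'   `deep_512`, with attributes `weights_source` and `seed`.
#' @export
embed_patches <- function(patches, spec = embedding_spec()) {
  stopifnot(inherits(spec, "embedding_spec"))
  if (spec$weights_source == "pretrained-natural-images")
    stop("pretrained natural-image weights are not available in this ",
         "package; use embedding_spec(weights_source = \"seeded-random\")")
  if (inherits(patches, "dhm_patches")) patches <- patches$patches
  mats <- lapply(patches, function(p)
    if (inherits(p, "cell_patch")) p$patch else p)
  if (!length(mats)) {
    out <- matrix(numeric(0), 0, spec$embed_dim)
    colnames(out) <- sprintf("deep_%03d", seq_len(spec$embed_dim))
    return(out)
  }
  dims <- unique(vapply(mats, function(m) paste(dim(m), collapse = "x"),
                        character(1)))
  if (length(dims) != 1) stop("patches must share one size; got ",
                              paste(dims, collapse = ", "))
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  net <- build_resnet18(spec, h, w)
  lo <- spec$input_range[1]; span <- diff(spec$input_range)
  out <- matrix(NA_real_, length(mats), spec$embed_dim)
  for (i in seq_along(mats)) {
    v <- (as.vector(mats[[i]]) - lo) / span
    out[i, ] <- resnet18_forward(net, matrix(v, length(v), 3))
  }
  colnames(out) <- sprintf("deep_%03d", seq_len(spec$embed_dim))
  attr(out, "weights_source") <- spec$weights_source
  attr(out, "seed") <- spec$seed
  out
}
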