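#' @useDynLib dhmpheno, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a global seed and a label
#'
#' Deterministic polynomial hash of `label` folded into `seed`, modulo
#' 2^31 - 1, so every pipeline stage gets an independent reproducible seed
#' that still fits in a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "background")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- as.double(abs(seed)) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

## run-length encoding of binary masks over the column-major linear index;
## compact text form "start:length;start:length;..." for sidecar files
encode_mask_rle <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  r <- rle(as.vector(mask != 0))
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values
  if (!any(keep)) return("")
  paste(sprintf("%d:%d", starts[keep], r$lengths[keep]), collapse = ";")
}

decode_mask_rle <- function(code, dim) {
  mask <- matrix(FALSE, dim[1], dim[2])
  if (!nzchar(code)) return(mask)
  parts <- strsplit(strsplit(code, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  for (p in parts) {
    s <- as.integer(p[1]); l <- as.integer(p[2])
    mask[s:(s + l - 1L)] <- TRUE
  }
  mask
}

## standardize columns; zero-variance columns are centred only
zscore_fit <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}

zscore_apply <- function(x, fit) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, fit$center, "-"), 2, fit$scale, "/")
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    keep <- vapply(features, is.numeric, logical(1))
    keep[names(features) %in% c("frame_id", "cell_id")] <- FALSE
    features <- as.matrix(features[, keep, drop = FALSE])
  }
  storage.mode(features) <- "double"
  features
}
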