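CLASSIFIER_METHODS <- c("random_forest", "svm", "knn", "neural_net")

normalize_method <- function(method) {
  method <- match.arg(tolower(method),
                      c(CLASSIFIER_METHODS, "rf", "nn", "k-nn", "knn5"))
  switch(method, rf = "random_forest", nn = "neural_net",
         `k-nn` = "knn", knn5 = "knn", method)
}

#' Balance classes by seeded random undersampling
#'
#' Every class is undersampled to the minority-class size so that accuracy
#' estimates are not inflated by class prevalence. Original row indices are
#' retained for provenance.
#'
#' @param features feature data frame or matrix (one row per cell).
#' @param labels class label per row.
#' @param seed integer seed.
#' @return list: `features`, `labels` (balanced subset, original row order),
#'   `indices` (rows of the input that were kept).
#' @export
balance_classes <- function(features, labels, seed = 1L) {
  lf <- if (is.factor(labels)) labels else factor(labels)
  stopifnot(NROW(features) == length(lf))
  tab <- table(lf)
  if (any(tab == 0)) stop("class with 0 cells: ",
                          names(tab)[which(tab == 0)[1]])
  if (length(tab) < 2) stop("need at least 2 classes, got ", length(tab))
  m <- min(tab)
  idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      i <- which(lf == cl)
      if (length(i) > m) sort(sample(i, m)) else i
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  list(features = features[idx, , drop = FALSE],
       labels = labels[idx], indices = idx)
}

## fit one classifier; x is a numeric matrix, y a factor.
## svm/knn/neural_net get z-scored inputs (fit on training data only);
## trees use raw features.
fit_one <- function(method, x, y, seed) {
  scaler <- NULL
  if (method %in% c("svm", "knn", "neural_net")) {
    scaler <- zscore_fit(x)
    x <- zscore_apply(x, scaler)
  }
  model <- switch(method,
    random_forest = with_seed(seed,
      randomForest::randomForest(x, y, ntree = 100)),
    svm = e1071::svm(x, y, kernel = "radial", cost = 1, scale = FALSE),
    knn = list(train = x, cl = y),
    neural_net = with_seed(seed, {
      targets <- nnet::class.ind(y)
      nnet::nnet(x, targets, size = 100, softmax = TRUE, maxit = 200,
                 MaxNWts = 1e6, decay = 0, trace = FALSE)
    }))
  list(method = method, model = model, scaler = scaler, levels = levels(y))
}

predict_one <- function(fit, x) {
  x <- as.matrix(x)
  if (!is.null(fit$scaler)) x <- zscore_apply(x, fit$scaler)
  pred <- switch(fit$method,
    random_forest = as.character(predict(fit$model, x)),
    svm = as.character(predict(fit$model, x)),
    knn = as.character(class::knn(fit$model$train, x, fit$model$cl, k = 5)),
    neural_net = {
      pr <- predict(fit$model, x)
      colnames(pr)[max.col(pr, ties.method = "first")]
    })
  factor(pred, levels = fit$levels)
}

#' Train a phenotype classifier on labelled cells
#'
#' Four fixed configurations mirror common practice for image-based
#' phenotyping: `random_forest` (100 trees, unbounded depth), `svm` (RBF
#' kernel, cost C = 1, one-against-one multi-class), `knn` (k = 5, Euclidean
#' distance on z-scored features), and `neural_net` (one hidden layer of 100
#' units, softmax/cross-entropy). Features are z-scored (fit on the training
#' data) for svm/knn/neural_net; trees use raw features.
#'
#' @param features numeric feature matrix or data frame (provenance columns
#'   `frame_id`/`cell_id` are dropped automatically).
#' @param labels class label per row.
#' @param method one of `"random_forest"`, `"svm"`, `"knn"`, `"neural_net"`
#'   (aliases `rf`, `nn` accepted).
#' @param seed integer seed (random forest bootstrap, network init).
#' @return object of class `dhm_classifier`.
#' @export
train_classifier <- function(features, labels,
                             method = "random_forest", seed = 1L) {
  method <- normalize_method(method)
  x <- as_feature_matrix(features)
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  fit <- fit_one(method, x, y, seed)
  structure(c(fit, list(feature_names = colnames(x), seed = seed)),
            class = "dhm_classifier")
}

#' @export
predict.dhm_classifier <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x)))
    x <- x[, object$feature_names, drop = FALSE]
  predict_one(object, x)
}

#' @export
print.dhm_classifier <- function(x, ...) {
  cat("<dhm_classifier>", x$method, "| classes:",
      paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified 5-fold cross-validated classification
#'
#' Cells are assigned to seeded stratified folds (per-class shuffling, folds
#' filled cyclically); each fold is held out once, the classifier is trained
#' on the remainder, and held-out accuracy (plain fraction correct) is
#' recorded. Input should already be balanced (see [balance_classes()]); a
#' warning is emitted otherwise.
#'
#' @param features numeric feature matrix or data frame.
#' @param labels class label per row.
#' @param method classifier method (see [train_classifier()]).
#' @param folds number of folds (default 5).
#' @param seed integer seed (fold assignment and per-fold training).
#' @return object of class `dhm_cv_report`: `method`, `fold_accuracies`,
#'   `median`, `quartiles`, `predictions` (row, fold, truth, predicted),
#'   `confusion` (aggregated over held-out folds), `class_balance_applied`,
#'   `seed`.
#' @export
cross_validate <- function(features, labels, method = "random_forest",
                           folds = 5L, seed = 1L) {
  method <- normalize_method(method)
  x <- as_feature_matrix(features)
  y <- factor(as.character(labels))
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < folds))
    stop("each class needs at least ", folds, " cells; got minimum ",
         min(tab))
  balanced <- length(unique(tab)) == 1
  if (!balanced)
    warning("class sizes differ (", paste(tab, collapse = "/"),
            "); consider balance_classes() first")
  fold_of <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in levels(y)) {
      i <- which(y == cl)
      fold_of[i[sample.int(length(i))]] <-
        rep_len(seq_len(folds), length(i))
    }
  })
  preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold_of != k
    fit <- fit_one(method, x[tr, , drop = FALSE], droplevels(y[tr]),
                   derive_seed(seed, paste0("fold", k)))
    fit$levels <- levels(y)
    p <- predict_one(fit, x[!tr, , drop = FALSE])
    preds[!tr] <- p
    acc[k] <- mean(p == y[!tr])
  }
  q <- stats::quantile(acc, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(method = method,
                 fold_accuracies = acc,
                 median = q[2], quartiles = c(lower = q[1], upper = q[3]),
                 predictions = data.frame(row = seq_along(y), fold = fold_of,
                                          truth = y, predicted = preds),
                 confusion = table(truth = y, predicted = preds),
                 class_balance_applied = balanced,
                 classes = levels(y), folds = folds, seed = seed),
            class = "dhm_cv_report")
}

#' @export
print.dhm_cv_report <- function(x, ...) {
  cat("<dhm_cv_report>", x$method, "|", x$folds, "folds | accuracy median",
      sprintf("%.3f", x$median),
      sprintf("(IQR %.3f-%.3f)\n", x$quartiles[1], x$quartiles[2]))
  cat("  folds:", paste(sprintf("%.3f", x$fold_accuracies), collapse = " "),
      "\n")
  print(x$confusion)
  invisible(x)
}

#' @export
summary.dhm_cv_report <- function(object, ...) {
  c(median = unname(object$median), lower_quartile = unname(object$quartiles[1]),
    upper_quartile = unname(object$quartiles[2]),
    mean = mean(object$fold_accuracies))
}

#' Quantify a mixed population with a pure-trained classifier
#'
#' Spike-in style composition estimation: a classifier trained only on pure
#' populations predicts every cell of a mixed sample, and the per-class
#' predicted fractions estimate the mixture composition.
#'
#' @param classifier a `dhm_classifier` trained on pure populations.
#' @param features feature rows of the mixed cells.
#' @return list: `fractions` (named, summing to 1), `counts`, `n`.
#' @export
quantify_mixture <- function(classifier, features) {
  stopifnot(inherits(classifier, "dhm_classifier"))
  if (NROW(features) == 0) stop("no cells to quantify")
  pred <- predict(classifier, features)
  counts <- table(pred)
  fr <- as.numeric(counts) / sum(counts)
  names(fr) <- names(counts)
  list(fractions = fr, counts = counts, n = sum(counts))
}
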