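make_labelled <- function(n_per_class, p = 5, gap = 0, seed = 1) {
  # two Gaussian classes separated by `gap` sds on every feature
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c("A", "B"), each = n_per_class))
}

test_that("balancing undersamples every class to the minority size", {
  d <- make_labelled(100)
  b <- balance_classes(d$x, d$y, seed = 3)
  expect_equal(table(b$labels), table(d$y))        # already balanced: no-op
  expect_equal(b$indices, seq_len(200))

  y3 <- c(rep("A", 300), rep("B", 100))
  x3 <- matrix(rnorm(400 * 3), ncol = 3)
  b3 <- balance_classes(x3, y3, seed = 3)
  expect_equal(unname(table(b3$labels)), c(100L, 100L), ignore_attr = TRUE)
  expect_equal(nrow(b3$features), 200)
  # kept rows really are the claimed originals
  expect_equal(b3$features, x3[b3$indices, ])

  b3b <- balance_classes(x3, y3, seed = 3)
  expect_identical(b3$indices, b3b$indices)        # seeded determinism
  b3c <- balance_classes(x3, y3, seed = 4)
  expect_false(identical(b3$indices, b3c$indices))
})

test_that("an empty class is rejected by name", {
  y <- factor(rep("A", 10), levels = c("A", "B"))
  expect_error(balance_classes(matrix(rnorm(20), 10), y, 1), "B")
  expect_error(balance_classes(matrix(rnorm(20), 10), rep("A", 10), 1),
               "at least 2 classes")
})

test_that("a cleanly separable feature yields near-perfect fold accuracies", {
  d <- make_labelled(60, p = 3, gap = 12, seed = 7)
  for (m in c("random_forest", "svm", "knn", "neural_net")) {
    rep <- cross_validate(d$x, d$y, method = m, seed = 11)
    expect_true(all(rep$fold_accuracies >= 0.99),
                label = paste(m, "fold accuracies"))
  }
})

test_that("cross-validation reports are complete and deterministic", {
  d <- make_labelled(50, gap = 1.5, seed = 9)
  rep1 <- cross_validate(d$x, d$y, method = "rf", seed = 21)
  expect_s3_class(rep1, "dhm_cv_report")
  expect_length(rep1$fold_accuracies, 5)
  expect_equal(sum(rep1$confusion), 100)           # every cell evaluated once
  expect_equal(unname(rep1$median),
               unname(stats::median(rep1$fold_accuracies)))
  rep2 <- cross_validate(d$x, d$y, method = "rf", seed = 21)
  expect_identical(rep1$fold_accuracies, rep2$fold_accuracies)
  expect_identical(rep1$predictions, rep2$predictions)
})

test_that("svm and knn are deterministic given the data order", {
  d <- make_labelled(40, gap = 1, seed = 5)
  for (m in c("svm", "knn")) {
    r1 <- cross_validate(d$x, d$y, method = m, seed = 8)
    r2 <- cross_validate(d$x, d$y, method = m, seed = 8)
    expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  }
})

test_that("permuted labels give chance-level accuracy for all methods", {
  # features carry no label signal: mean CV accuracy must sit in the 95%
  # permutation-null band [0.45, 0.55]. The plain binomial band is too
  # narrow here because held-out predictions share training data across
  # folds, inflating the null sd of CV accuracy by roughly a third.
  # all four methods are exercised at this scale in the acceptance suite;
  # here the fast pair keeps the module test quick
  n <- 500
  d <- make_labelled(n, p = 8, gap = 0, seed = 13)
  for (m in c("random_forest", "knn")) {
    rep <- cross_validate(d$x, d$y, method = m, seed = 17)
    acc <- mean(rep$fold_accuracies)
    expect_gte(acc, 0.45)
    expect_lte(acc, 0.55)
  }
})

test_that("imbalanced input triggers a warning", {
  x <- matrix(rnorm(300 * 2), ncol = 2)
  y <- c(rep("A", 200), rep("B", 100))
  expect_warning(cross_validate(x, y, method = "knn", seed = 1),
                 "class sizes differ")
})

test_that("mixture quantification returns normalized fractions", {
  d <- make_labelled(100, p = 3, gap = 10, seed = 19)
  clf <- train_classifier(d$x, d$y, "random_forest", seed = 23)

  # pure class-A cells from the same generator: fraction_A = 1
  set.seed(31)
  xa <- matrix(rnorm(50 * 3), ncol = 3); colnames(xa) <- colnames(d$x)
  qa <- quantify_mixture(clf, xa)
  expect_equal(unname(qa$fractions["A"]), 1)
  expect_equal(sum(qa$fractions), 1)

  # a known 30/70 blend is recovered (the classes are widely separated)
  xb <- rbind(matrix(rnorm(30 * 3), ncol = 3),
              matrix(rnorm(70 * 3, mean = 10), ncol = 3))
  colnames(xb) <- colnames(d$x)
  qb <- quantify_mixture(clf, xb)
  expect_equal(unname(qb$fractions["B"]), 0.7, tolerance = 0.02)
  expect_equal(sum(qb$fractions), 1)

  expect_error(quantify_mixture(clf, d$x[0, ]), "no cells")
})

test_that("duplicating majority-class rows does not break balancing", {
  x <- matrix(rnorm(150 * 3), ncol = 3)
  y <- c(rep("A", 50), rep("B", 100))
  xd <- rbind(x, x[51:150, ]); yd <- c(y, y[51:150])
  b <- balance_classes(xd, yd, seed = 2)
  expect_equal(unname(table(b$labels)), c(50L, 50L), ignore_attr = TRUE)
})
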