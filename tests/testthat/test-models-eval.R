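test_that("stratified holdout splits 80/20 per class, disjoint and reproducible", {
  y <- factor(rep(c("anxious", "non_anxious"), each = 50))
  sp <- holdout_split(y, 0.8, seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_equal(as.vector(table(y[sp$train])), c(40L, 40L))
  expect_equal(as.vector(table(y[sp$test])), c(10L, 10L))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(sp, holdout_split(y, 0.8, seed = 1))
  expect_false(identical(sp, holdout_split(y, 0.8, seed = 2)))
  expect_error(holdout_split(factor(c("anxious", "non_anxious", "non_anxious"))),
               "at least 2")
})

test_that("Cohen's kappa reproduces hand computations", {
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.5)
  expect_equal(cohen_kappa(c("a", "b", "a", "b"), c("a", "b", "a", "b")), 1)
  # independence at 50/50 marginals with agreement exactly at chance
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_warning(k <- cohen_kappa(c(1, 1), c(1, 1)), "degenerate")
  expect_equal(k, 1)
  expect_error(cohen_kappa(1:3, 1:4), "equal length")
})

test_that("rank AUC is antisymmetric under score negation", {
  set.seed(11)
  for (i in 1:20) {
    y <- factor(sample(c("anxious", "non_anxious"), 30, replace = TRUE),
                levels = c("non_anxious", "anxious"))
    if (nlevels(droplevels(y)) < 2) next
    s <- rnorm(30)
    expect_equal(anxeeg:::auc_rank(s, y), 1 - anxeeg:::auc_rank(-s, y),
                 tolerance = 1e-12)
  }
})

test_that("accuracy recomputed from the confusion matrix matches the report", {
  blobs <- make_blobs(5, n_per_class = 40)
  rep <- evaluate_classifier(classifier_spec("lda"), blobs$x, blobs$y, seed = 2)
  conf <- rep$confusion
  expect_equal(sum(conf), 16)
  expect_equal(rep$accuracy, sum(diag(conf)) / sum(conf))
  expect_equal(rep$recall_micro, rep$accuracy)
})

test_that("every classifier separates well-separated blobs (> 0.95 test accuracy)", {
  blobs <- make_blobs(1, n_per_class = 60)
  for (spec in default_classifier_specs()) {
    rep <- evaluate_classifier(spec, blobs$x, blobs$y, seed = 3)
    expect_gt(rep$accuracy, 0.95)
    expect_gt(rep$auc, 0.95)
    expect_gt(rep$kappa, 0.9)
    expect_equal(rep$recall_micro, rep$accuracy)
  }
})

test_that("1-NN memorizes its own training set", {
  blobs <- make_blobs(2, n_per_class = 30, shift = 1)
  model <- train_classifier(classifier_spec("knn"), blobs$x, blobs$y)
  pred <- predict(model, blobs$x)
  expect_equal(mean(pred$class == blobs$y), 1)
})

test_that("seeded stochastic learners give identical predictions on refit", {
  blobs <- make_blobs(3, n_per_class = 30, shift = 2)
  for (nm in c("rf", "adaboost", "gradient_boost")) {
    m1 <- train_classifier(classifier_spec(nm), blobs$x, blobs$y, seed = 7)
    m2 <- train_classifier(classifier_spec(nm), blobs$x, blobs$y, seed = 7)
    expect_identical(predict(m1, blobs$x)$score, predict(m2, blobs$x)$score)
  }
  expect_error(train_classifier(classifier_spec("rf"), blobs$x,
                                factor(rep("anxious", 60),
                                       levels = c("non_anxious", "anxious"))),
               "both classes")
  expect_error(classifier_spec("mystery"), "unknown classifier")
})

test_that("perfect and degenerate predictions give the expected metric values", {
  # perfect predictions via an lda on trivially separated data
  set.seed(8)
  x <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)), ncol = 1)
  colnames(x) <- "f1"
  y <- factor(rep(c("non_anxious", "anxious"), each = 20),
              levels = c("non_anxious", "anxious"))
  rep <- evaluate_classifier(classifier_spec("lda"), x, y, seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$precision_weighted, 1)
  expect_equal(rep$kappa, 1)
  expect_equal(rep$auc, 1)
})

test_that("the scaler is fitted on the training split only (no test leakage)", {
  set.seed(21)
  x <- matrix(rnorm(100), ncol = 1)
  sc_train <- anxeeg:::fit_scaler(x[1:80, , drop = FALSE])
  sc_all <- anxeeg:::fit_scaler(x)
  shifted_test <- x[81:100, , drop = FALSE] + 5
  expect_false(isTRUE(all.equal(
    anxeeg:::apply_scaler(sc_train, shifted_test),
    anxeeg:::apply_scaler(sc_all, shifted_test))))
})

test_that("the comparison grid covers 6 classifiers x 2 features x 2 labelings x 2 balancing", {
  blobs <- make_blobs(4, n_per_class = 25)
  feats <- list(dwt = blobs$x, psd = blobs$x[, 1:3])
  labels <- list(sam = blobs$y, hama = blobs$y)
  cmp <- run_comparison(feats, labels, seed = 5)
  expect_equal(nrow(cmp$grid), 48)
  expect_length(cmp$reports, 48)
  expect_equal(sort(unique(cmp$grid$classifier)),
               sort(names(default_classifier_specs())))
  expect_true(all(cmp$grid$recall == cmp$grid$accuracy))
  expect_true(all(cmp$grid$auc >= 0 & cmp$grid$auc <= 1))
  expect_true(all(cmp$grid$kappa >= -1 & cmp$grid$kappa <= 1))
})
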