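#' @title Classifier benchmarking and evaluation metrics
#' @name models_eval
NULL

POSITIVE_CLASS <- "anxious"

#' Classifier specification
#'
#' Supported names and default hyperparameters: `knn` (neighbors = 1), `lda`
#' (components = 1), `svm` (RBF kernel), `rf` (500 trees), `adaboost` (100
#' stump rounds), `gradient_boost` (100 rounds, depth 3, learning rate 0.1).
#'
#' @param name one of `"knn"`, `"lda"`, `"svm"`, `"rf"`, `"adaboost"`,
#'   `"gradient_boost"`.
#' @param ... hyperparameter overrides.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(name, ...) {
  defaults <- list(
    knn = list(neighbors = 1),
    lda = list(components = 1),
    svm = list(kernel = "radial"),
    rf = list(trees = 500),
    adaboost = list(estimators = 100, max_depth = 1),
    gradient_boost = list(estimators = 100, max_depth = 3, learning_rate = 0.1))
  if (!name %in% names(defaults))
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE)
  hp <- utils::modifyList(defaults[[name]], list(...))
  structure(list(name = name, hyperparameters = hp), class = "classifier_spec")
}

#' The six benchmarked classifiers with their default hyperparameters
#' @return named list of `classifier_spec`.
#' @export
default_classifier_specs <- function() {
  nm <- c("knn", "lda", "svm", "rf", "adaboost", "gradient_boost")
  stats::setNames(lapply(nm, classifier_spec), nm)
}

#' Stratified holdout split
#'
#' @param n_rows number of rows, or a vector of row indices.
#' @param y binary factor of labels.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(y, train_fraction = 0.8, seed = 1L) {
  y <- factor(y)
  if (any(table(y) < 2))
    stop("each class needs at least 2 rows to split", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    sample(idx, round(train_fraction * length(idx)))
  }))
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$mean, scale = scaler$sd)[, , drop = FALSE]
}

#' Train one classifier
#'
#' Expects standardized features (fit the scaler on the training split only;
#' [evaluate_classifier()] handles this).
#'
#' @param spec a [classifier_spec()].
#' @param x numeric training matrix (standardized).
#' @param y binary factor aligned with `x`.
#' @param seed seed for stochastic learners (forests, boosting draws).
#' @return an `anx_model` exposing class predictions and a continuous score.
#' @export
train_classifier <- function(spec, x, y, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nrow(x) == 0 || nlevels(y) != 2 || any(table(y) == 0))
    stop("training set must be non-empty with both classes present", call. = FALSE)
  hp <- spec$hyperparameters
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- switch(spec$name,
    knn = list(x = x, y = y, k = hp$neighbors),
    lda = {
      # LDA is undefined for features constant within every class (e.g. an
      # attribute that is structurally zero); drop them, remember the kept set
      pooled_sd <- sqrt(Reduce(`+`, lapply(levels(y), function(lv) {
        xi <- x[y == lv, , drop = FALSE]
        colSums(scale(xi, scale = FALSE)^2)
      })) / nrow(x))
      keep <- which(pooled_sd > 1e-8)
      if (length(keep) < 1) stop("no informative features for LDA", call. = FALSE)
      fit <- withCallingHandlers(
        MASS::lda(x[, keep, drop = FALSE], grouping = y),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      list(fit = fit, keep = keep)
    },
    svm = e1071::svm(x, y, kernel = hp$kernel, scale = FALSE),
    rf = randomForest::randomForest(x, y, ntree = hp$trees),
    adaboost = fit_adaboost(x, y, n_rounds = hp$estimators,
                            max_depth = hp$max_depth),
    gradient_boost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == POSITIVE_CLASS))
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = hp$max_depth,
                                       eta = hp$learning_rate,
                                       nthread = 1, seed = seed),
                         data = dtrain, nrounds = hp$estimators, verbose = 0)
    },
    stop(sprintf("unknown classifier '%s'", spec$name), call. = FALSE))
  structure(list(spec = spec, fit = fit, levels = levels(y), seed = seed),
            class = "anx_model")
}

# AdaBoost.M1 over rpart stumps; score is the weighted vote margin
fit_adaboost <- function(x, y, n_rounds = 100, max_depth = 1) {
  dat <- data.frame(.y = y, x, check.names = FALSE)
  n <- nrow(dat)
  w <- rep(1 / n, n)
  ysign <- ifelse(y == POSITIVE_CLASS, 1, -1)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, dat, type = "class")
    hsign <- ifelse(pred == POSITIVE_CLASS, 1, -1)
    err <- sum(w[hsign != ysign]) / sum(w)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(-alpha * ysign * hsign)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, x) {
  dat <- as.data.frame(x, check.names = FALSE)
  score <- numeric(nrow(dat))
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], dat, type = "class")
    score <- score + fit$alphas[m] * ifelse(pred == POSITIVE_CLASS, 1, -1)
  }
  score
}

#' Predict classes and scores from a fitted model
#'
#' @param object an `anx_model`.
#' @param newdata numeric matrix (standardized with the training scaler).
#' @param ... unused.
#' @return list with `class` (factor) and `score` (continuous score oriented
#'   toward the anxious class, used for ROC).
#' @export
predict.anx_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  lv <- object$levels
  score <- switch(object$spec$name,
    knn = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(object$seed)
      pr <- class::knn(object$fit$x, x, object$fit$y, k = object$fit$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == POSITIVE_CLASS, p, 1 - p)
    },
    lda = predict(object$fit$fit,
                  x[, object$fit$keep, drop = FALSE])$posterior[, POSITIVE_CLASS],
    svm = {
      pr <- predict(object$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      parts <- strsplit(colnames(dv)[1], "/")[[1]]
      if (parts[1] == POSITIVE_CLASS) dv[, 1] else -dv[, 1]
    },
    rf = predict(object$fit, x, type = "prob")[, POSITIVE_CLASS],
    adaboost = predict_adaboost(object$fit, x),
    gradient_boost = predict(object$fit, xgboost::xgb.DMatrix(x)))
  threshold <- if (object$spec$name %in% c("svm", "adaboost")) 0 else 0.5
  cls <- factor(ifelse(score > threshold, POSITIVE_CLASS,
                       setdiff(lv, POSITIVE_CLASS)), levels = lv)
  list(class = cls, score = as.numeric(score))
}

#' Cohen's kappa agreement coefficient
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e` the chance agreement expected from the marginal label frequencies.
#' When both raters use a single identical label (`p_e = 1`), 1 is returned by
#' convention with a warning.
#'
#' @param actual,predicted equal-length label vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("label vectors must have equal length", call. = FALSE)
  lv <- union(unique(as.character(actual)), unique(as.character(predicted)))
  a <- factor(actual, levels = lv)
  p <- factor(predicted, levels = lv)
  po <- mean(a == p)
  pe <- sum(prop.table(table(a)) * prop.table(table(p)))
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("degenerate single-class agreement; returning kappa = 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

# rank-statistic AUC (Mann-Whitney with mid-ranks for ties)
auc_rank <- function(score, y) {
  pos <- y == POSITIVE_CLASS
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("single-class test set; AUC undefined")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted model on a test set
#'
#' @param model an `anx_model`.
#' @param x_test standardized test matrix.
#' @param y_test binary factor of actual labels.
#' @return an `evaluation_report`: accuracy, micro-averaged recall (identical
#'   to accuracy by construction), support-weighted precision, 2x2 confusion
#'   matrix (rows = actual, columns = predicted), rank-statistic AUC and
#'   Cohen's kappa.
#' @export
evaluate_model <- function(model, x_test, y_test) {
  if (length(y_test) == 0) stop("empty test set", call. = FALSE)
  y_test <- factor(y_test, levels = model$levels)
  pred <- predict(model, x_test)
  conf <- table(actual = y_test, predicted = pred$class)
  acc <- mean(pred$class == y_test)
  prec_by_class <- vapply(model$levels, function(lv) {
    denom <- sum(pred$class == lv)
    if (denom == 0) 0 else sum(pred$class == lv & y_test == lv) / denom
  }, 0)
  support <- prop.table(table(y_test))
  structure(list(classifier = model$spec,
                 accuracy = acc,
                 recall_micro = acc,
                 precision_weighted = sum(prec_by_class * as.numeric(support)),
                 confusion = conf,
                 auc = auc_rank(pred$score, y_test),
                 kappa = cohen_kappa(y_test, pred$class)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: accuracy %.3f, precision %.3f, AUC %s, kappa %.3f\n",
              x$classifier$name, x$accuracy, x$precision_weighted,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$kappa))
  invisible(x)
}

#' Split, scale, optionally balance, train and evaluate one classifier
#'
#' The z-score scaler is fitted on the training split only; when
#' `smote = TRUE` the training split (never the test split) is balanced with
#' [smote()] before fitting, unless `smote_before_split` reproduces the
#' leakier balance-then-split variant.
#'
#' @param spec a [classifier_spec()].
#' @param x feature matrix.
#' @param y binary factor of labels.
#' @param train_fraction holdout training fraction (default 0.8).
#' @param seed seed driving the split, SMOTE draws and stochastic learners.
#' @param smote balance the training data?
#' @param smote_k SMOTE neighbour count.
#' @param smote_before_split apply SMOTE to the full table before splitting?
#' @return an `evaluation_report` (with `split_seed` recorded).
#' @export
evaluate_classifier <- function(spec, x, y, train_fraction = 0.8, seed = 1L,
                                smote = FALSE, smote_k = 5,
                                smote_before_split = FALSE) {
  x <- as.matrix(x)
  y <- factor(y)
  if (smote && smote_before_split) {
    bal <- smote(x, y, k = smote_k, seed = seed)
    x <- bal$x
    y <- bal$y
    smote <- FALSE
  }
  sp <- holdout_split(y, train_fraction, seed)
  x_tr <- x[sp$train, , drop = FALSE]
  y_tr <- y[sp$train]
  if (smote) {
    bal <- smote(x_tr, y_tr, k = smote_k, seed = seed)
    x_tr <- bal$x
    y_tr <- bal$y
  }
  scaler <- fit_scaler(x_tr)
  model <- train_classifier(spec, apply_scaler(scaler, x_tr), y_tr, seed = seed)
  rep <- evaluate_model(model, apply_scaler(scaler, x[sp$test, , drop = FALSE]),
                        y[sp$test])
  rep$split_seed <- seed
  rep
}

#' Benchmark the classifier grid over feature sets, labelings and balancing
#'
#' Runs every classifier on every combination of feature set (wavelet,
#' spectral), labeling scheme (SAM, HAM-A) and SMOTE on/off — 6 x 2 x 2 x 2 =
#' 48 evaluation reports with the default inputs.
#'
#' @param features named list of feature matrices (e.g. `dwt`, `psd`), all
#'   row-aligned with the labels.
#' @param labels named list of binary label factors (e.g. `sam`, `hama`).
#' @param specs list of [classifier_spec()] (default all six).
#' @param train_fraction holdout training fraction.
#' @param seed integer seed.
#' @param smote_k SMOTE neighbour count.
#' @return list with `grid` (tidy data frame of metrics) and `reports` (the
#'   `evaluation_report` objects, named `features.labeling.smote.classifier`).
#' @export
run_comparison <- function(features, labels, specs = default_classifier_specs(),
                           train_fraction = 0.8, seed = 1L, smote_k = 5) {
  combos <- expand.grid(classifier = names(specs),
                        features = names(features),
                        labeling = names(labels),
                        smote = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  reports <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    reports[[i]] <- evaluate_classifier(
      specs[[co$classifier]], features[[co$features]], labels[[co$labeling]],
      train_fraction = train_fraction, seed = seed,
      smote = co$smote, smote_k = smote_k)
  }
  names(reports) <- with(combos, paste(features, labeling,
                                       ifelse(smote, "smote", "raw"),
                                       classifier, sep = "."))
  grid <- cbind(combos,
                accuracy = vapply(reports, `[[`, 0, "accuracy"),
                recall = vapply(reports, `[[`, 0, "recall_micro"),
                precision = vapply(reports, `[[`, 0, "precision_weighted"),
                auc = vapply(reports, `[[`, 0, "auc"),
                kappa = vapply(reports, `[[`, 0, "kappa"))
  rownames(grid) <- NULL
  list(grid = grid, reports = reports)
}
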