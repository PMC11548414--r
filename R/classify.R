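# Stratified splitting, LDA/SVM/MLP training, and evaluation with
# confusion matrices and per-class accuracies.

#' Stratified train/validation split
#'
#' Splits a feature matrix 75:25 (by default) within each class. At
#' `level = "trial"` (recommended) whole trials are assigned to one side,
#' so overlapping sliding windows of the same trial can never straddle the
#' split; `level = "segment"` splits individual rows.
#'
#' @param features An `ssvep_features` data frame (or any data frame with
#'   `label` and `trial` columns).
#' @param train_fraction Fraction assigned to training (default 0.75).
#' @param level `"trial"` (default) or `"segment"`.
#' @param seed Seed for the per-class permutation.
#' @return List with `train` and `validation` data frames (disjoint,
#'   exhaustive) and `train_trials` / `validation_trials` when
#'   `level = "trial"`.
#' @export
stratified_split <- function(features, train_fraction = 0.75,
                             level = c("trial", "segment"), seed = NULL) {
  level <- match.arg(level)
  if (!all(c("label", "trial") %in% names(features)))
    stopf("`features` must have `label` and `trial` columns")
  if (!(train_fraction > 0 && train_fraction < 1))
    stopf("`train_fraction` must lie in (0, 1)")
  labs <- as.character(features$label)
  classes <- unique(labs)
  if (level == "segment") {
    too_small <- classes[table(labs)[classes] < 4]
    if (length(too_small))
      stopf("class(es) with fewer than 4 rows: %s",
            paste(too_small, collapse = ", "))
  }
  with_seed(seed, {
    if (level == "trial") {
      tr_class <- tapply(labs, features$trial, `[`, 1)
      trials <- as.integer(names(tr_class))
      train_trials <- integer()
      for (cl in classes) {
        cls_trials <- trials[tr_class == cl]
        if (length(cls_trials) < 2)
          stopf("class '%s' has fewer than 2 trials; cannot split at trial level", cl)
        n_tr <- max(1L, min(length(cls_trials) - 1L,
                            round(train_fraction * length(cls_trials))))
        train_trials <- c(train_trials, sample(cls_trials, n_tr))
      }
      in_train <- features$trial %in% train_trials
      list(train = features[in_train, , drop = FALSE],
           validation = features[!in_train, , drop = FALSE],
           train_trials = sort(train_trials),
           validation_trials = sort(setdiff(trials, train_trials)))
    } else {
      idx_train <- integer()
      for (cl in classes) {
        rows <- which(labs == cl)
        n_tr <- max(1L, min(length(rows) - 1L,
                            round(train_fraction * length(rows))))
        idx_train <- c(idx_train, sample(rows, n_tr))
      }
      idx_train <- sort(idx_train)
      list(train = features[idx_train, , drop = FALSE],
           validation = features[-idx_train, , drop = FALSE])
    }
  })
}

#' Train a direction classifier on CSP features
#'
#' Fits one of three classifiers on z-scored features (standardization
#' statistics computed on the training rows only and stored with the
#' model):
#' * `"lda"`: linear discriminant analysis ([MASS::lda()]; falls back to a
#'   small ridge on the features if the within-class covariance is
#'   singular);
#' * `"svm"`: support vector machine with RBF kernel
#'   ([e1071::svm()]; `cost = 1`,
#'   `gamma = 1/(d * mean feature variance)`);
#' * `"mlp"`: single-hidden-layer perceptron
#'   ([nnet::nnet()]; 32 hidden units, softmax output, at most 500
#'   iterations, seeded initial weights).
#'
#' @param train Training `ssvep_features` rows.
#' @param method `"lda"`, `"svm"` or `"mlp"`.
#' @param hyper Optional named list overriding defaults (`cost`, `gamma`
#'   for svm; `size`, `decay`, `maxit` for mlp).
#' @param seed Seed for methods with random initialization (mlp).
#' @return An object of class `ssvep_classifier` with a [predict] method.
#' @export
train_classifier <- function(train, method = c("lda", "svm", "mlp"),
                             hyper = list(), seed = NULL) {
  method <- match.arg(method)
  if (!nrow(train)) stopf("training set is empty")
  classes <- names(direction_frequencies())
  y <- factor(as.character(train$label), levels = classes)
  if (length(unique(y)) < 2)
    stopf("training data contains a single class ('%s')", unique(as.character(y)))
  cols <- feature_columns(train)
  X <- as.matrix(train[, cols, drop = FALSE])
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- scale(X, center = center, scale = scale_)

  fit <- switch(method,
    lda = {
      tryCatch(MASS::lda(Xs, grouping = y),
               error = function(e) {
                 Xr <- Xs + matrix(stats::rnorm(length(Xs), sd = 1e-8), nrow(Xs))
                 MASS::lda(Xr, grouping = y)
               })
    },
    svm = {
      cost <- if (!is.null(hyper$cost)) hyper$cost else 1
      gamma <- if (!is.null(hyper$gamma)) hyper$gamma else
        1 / (ncol(Xs) * mean(apply(Xs, 2, stats::var)))
      e1071::svm(Xs, y, kernel = "radial", cost = cost, gamma = gamma,
                 scale = FALSE)
    },
    mlp = {
      size <- if (!is.null(hyper$size)) hyper$size else 32
      decay <- if (!is.null(hyper$decay)) hyper$decay else 1e-4
      maxit <- if (!is.null(hyper$maxit)) hyper$maxit else 500
      with_seed(if (is.null(seed)) 1L else seed,
        nnet::nnet(Xs, nnet::class.ind(y), size = size, decay = decay,
                   maxit = maxit, softmax = TRUE, trace = FALSE,
                   MaxNWts = 100000))
    })
  structure(
    list(method = method, fit = fit, center = center, scale = scale_,
         feature_names = cols, classes = classes, seed = seed),
    class = "ssvep_classifier"
  )
}

#' @export
print.ssvep_classifier <- function(x, ...) {
  cat(sprintf("<ssvep_classifier> %s on %d features, classes: %s\n",
              toupper(x$method), length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict directions for feature rows
#'
#' @param object An [train_classifier()] model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted directions (canonical level order).
#' @export
predict.ssvep_classifier <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stopf("newdata lacks feature column(s): %s", paste(missing, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Xs <- scale(X, center = object$center, scale = object$scale)
  pred <- switch(object$method,
    lda = as.character(stats::predict(object$fit, Xs)$class),
    svm = as.character(stats::predict(object$fit, Xs)),
    mlp = {
      p <- stats::predict(object$fit, Xs)
      colnames(p)[max.col(p, ties.method = "first")]
    })
  factor(pred, levels = object$classes)
}

#' Evaluate a classifier on validation rows
#'
#' Builds the 4 x 4 confusion matrix (rows = true direction, columns =
#' predicted) and reports per-class accuracies (diagonal / row sum), their
#' unweighted mean (`average_accuracy`, the headline metric), and the
#' overall accuracy (trace / total). At `level = "trial"` the prediction
#' for each trial is the majority vote over its segments (ties broken by
#' canonical class order) and counts are per trial.
#'
#' @param model An [train_classifier()] model.
#' @param validation Validation `ssvep_features` rows.
#' @param level `"segment"` (default) or `"trial"`.
#' @return An object of class `ssvep_eval`: list with `confusion`,
#'   `per_class_accuracy`, `average_accuracy`, `overall_accuracy`,
#'   `n`, `level`, `method`.
#' @export
evaluate_classifier <- function(model, validation, level = c("segment", "trial")) {
  level <- match.arg(level)
  stopifnot(inherits(model, "ssvep_classifier"))
  if (!nrow(validation)) stopf("validation set is empty")
  classes <- model$classes
  pred <- predict(model, validation)
  truth <- factor(as.character(validation$label), levels = classes)
  if (level == "trial") {
    agg <- tapply(seq_len(nrow(validation)), validation$trial, function(ix) {
      votes <- table(factor(as.character(pred[ix]), levels = classes))
      list(pred = classes[which.max(votes)], truth = as.character(truth[ix[1]]))
    })
    pred <- factor(vapply(agg, `[[`, character(1), "pred"), levels = classes)
    truth <- factor(vapply(agg, `[[`, character(1), "truth"), levels = classes)
  }
  confusion <- table(truth = truth, predicted = pred)
  confusion <- unclass(confusion)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(
    list(confusion = confusion,
         per_class_accuracy = per_class,
         average_accuracy = mean(per_class),
         overall_accuracy = sum(diag(confusion)) / sum(confusion),
         n = sum(confusion), level = level, method = model$method),
    class = "ssvep_eval"
  )
}

#' @export
print.ssvep_eval <- function(x, ...) {
  cat(sprintf("<ssvep_eval> %s, %s level, n=%d | average accuracy %.2f%% (overall %.2f%%)\n",
              toupper(x$method), x$level, x$n, 100 * x$average_accuracy,
              100 * x$overall_accuracy))
  print(x$confusion)
  invisible(x)
}
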