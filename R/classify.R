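classifier_families <- c("random-forest", "gradient-boosted-trees",
                         "gaussian-naive-bayes", "neural-net")

default_hyperparameters <- function(family) {
  switch(family,
    "random-forest" = list(n_estimators = 100L, criterion = "gini",
                           min_samples_split = 2L, min_samples_leaf = 1L),
    "gradient-boosted-trees" = list(booster = "gbtree", learning_rate = 0.3,
                                    min_split_loss = 0, max_depth = 6L,
                                    sampling_method = "uniform",
                                    n_rounds = 100L),
    "gaussian-naive-bayes" = list(priors = NULL, var_smoothing = 1e-9),
    "neural-net" = list(units = c(32L, 16L, 1L),
                        activations = c("relu", "relu", "sigmoid"),
                        epochs = 200L, learning_rate = 0.01,
                        standardize = TRUE)
  )
}

#' Classifier specification
#'
#' Declares one of the four classifier families with its hyperparameters.
#' Defaults follow the settings used in the screening study: random forest
#' with 100 Gini trees; gradient-boosted trees (gbtree booster, learning
#' rate 0.3, no minimum split loss, depth 6, uniform sampling); Gaussian
#' naive Bayes with empirical priors and variance smoothing 1e-9; and a
#' dense 32/16/1 ReLU+sigmoid network trained for 200 epochs. Unknown
#' hyperparameter names are rejected.
#'
#' @param family One of `"random-forest"`, `"gradient-boosted-trees"`,
#'   `"gaussian-naive-bayes"`, `"neural-net"`.
#' @param hyperparameters Named list of overrides of the family defaults.
#' @param seed Integer seed used when fitting.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = classifier_families,
                            hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  hp <- default_hyperparameters(family)
  if (length(hyperparameters)) {
    unknown <- setdiff(names(hyperparameters), names(hp))
    if (length(unknown)) {
      stop("unknown hyperparameters for ", family, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    hp[names(hyperparameters)] <- hyperparameters
  }
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier spec:", x$family, sprintf("(seed %d)\n", x$seed))
  hp <- x$hyperparameters
  for (nm in names(hp)) {
    cat(sprintf("  %s = %s\n", nm,
                paste(format(hp[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

dataset_xy <- function(data) {
  feats <- if (inherits(data, "labeled_dataset")) data$features else data
  fcols <- paste0("F", 1:17)
  missing_cols <- setdiff(fcols, names(feats))
  if (length(missing_cols)) {
    stop("feature columns missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(feats[fcols])
  if (!all(is.finite(x))) stop("features F1-F17 must be finite", call. = FALSE)
  y <- feats$F18
  if (is.null(y)) stop("target column F18 is missing", call. = FALSE)
  list(x = x, y = as.integer(y))
}

#' Fit a classifier to a labeled feature dataset
#'
#' Trains one classifier on the F1-F17 feature columns with F18 as the
#' binary target (1 = cancer, positive class). Tree and Bayes families are
#' deterministic given the spec's seed. Variance smoothing for naive Bayes
#' adds `var_smoothing * max feature variance` to every class-conditional
#' variance. The neural family standardises features internally; the other
#' families use the raw features.
#'
#' @param spec A [classifier_spec()].
#' @param data A `labeled_dataset` (or a data frame with `F1`..`F18`);
#'   both classes must be present.
#' @return An object of class `fp_classifier` with a [predict][predict.fp_classifier] method.
#' @export
fit_classifier <- function(spec, data) {
  if (!inherits(spec, "classifier_spec")) {
    stop("`spec` must be a classifier_spec", call. = FALSE)
  }
  xy <- dataset_xy(data)
  if (length(unique(xy$y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    "random-forest" = with_seed(spec$seed,
      randomForest::randomForest(
        x = xy$x, y = factor(xy$y, levels = c(0L, 1L)),
        ntree = hp$n_estimators, nodesize = hp$min_samples_leaf)),
    "gradient-boosted-trees" = {
      dtrain <- xgboost::xgb.DMatrix(xy$x, label = xy$y, nthread = 1)
      with_seed(spec$seed, xgboost::xgb.train(
        params = list(booster = hp$booster, eta = hp$learning_rate,
                      gamma = hp$min_split_loss, max_depth = hp$max_depth,
                      subsample = 1, objective = "binary:logistic",
                      nthread = 1),
        data = dtrain, nrounds = hp$n_rounds, verbose = 0))
    },
    "gaussian-naive-bayes" = {
      nb <- e1071::naiveBayes(x = as.data.frame(xy$x),
                              y = factor(xy$y, levels = c(0L, 1L)))
      if (!is.null(hp$priors)) {
        nb$apriori <- stats::setNames(
          as.table(hp$priors * length(xy$y)), levels(nb$levels))
      }
      # variance smoothing: sd' = sqrt(sd^2 + eps * max feature variance);
      # a single-observation class has sd NA, treated as 0 before smoothing
      max_var <- max(apply(xy$x, 2L, stats::var))
      nb$tables <- lapply(nb$tables, function(tab) {
        s <- tab[, 2L]
        s[is.na(s)] <- 0
        tab[, 2L] <- sqrt(s^2 + hp$var_smoothing * max_var)
        tab
      })
      nb
    },
    "neural-net" = {
      center <- if (hp$standardize) colMeans(xy$x) else rep(0, ncol(xy$x))
      scale_ <- if (hp$standardize) {
        s <- apply(xy$x, 2L, stats::sd)
        ifelse(s > 0, s, 1)
      } else rep(1, ncol(xy$x))
      xs <- scale(xy$x, center = center, scale = scale_)
      net <- mlp_train(xs, matrix(xy$y, ncol = 1L), units = hp$units,
                       activations = hp$activations, epochs = hp$epochs,
                       learning_rate = hp$learning_rate, seed = spec$seed)
      list(net = net, center = center, scale = scale_)
    }
  )
  structure(list(spec = spec, fit = fit,
                 feature_names = colnames(xy$x)),
            class = "fp_classifier")
}

#' Predict classes or probabilities from a fitted classifier
#'
#' @param object An `fp_classifier` from [fit_classifier()].
#' @param newdata A `labeled_dataset` or data frame with `F1`..`F17`.
#' @param type `"class"` for 0/1 labels, `"prob"` for the probability of the
#'   positive (cancer) class.
#' @param ... Unused.
#' @return Integer classes or numeric probabilities, one per row.
#' @export
predict.fp_classifier <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  feats <- if (inherits(newdata, "labeled_dataset")) {
    newdata$features
  } else {
    newdata
  }
  missing_cols <- setdiff(object$feature_names, names(feats))
  if (length(missing_cols)) {
    stop("feature dimension mismatch; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(feats[object$feature_names])
  prob <- switch(object$spec$family,
    "random-forest" =
      stats::predict(object$fit, x, type = "prob")[, "1"],
    "gradient-boosted-trees" =
      stats::predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    "gaussian-naive-bayes" =
      stats::predict(object$fit, as.data.frame(x), type = "raw")[, "1"],
    "neural-net" = {
      xs <- scale(x, center = object$fit$center, scale = object$fit$scale)
      mlp_predict_prob(object$fit$net, xs)
    }
  )
  if (type == "prob") as.numeric(prob) else as.integer(prob >= 0.5)
}

#' Confusion matrix
#'
#' Binary confusion counts in the screening orientation: the positive class
#' is cancer (1). `TP` = cancer classified as cancer, `FP` = healthy
#' classified as cancer, `FN` = cancer classified as healthy, `TN` = healthy
#' classified as healthy.
#'
#' @param TP,FP,FN,TN Non-negative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L,
              dimnames = list(actual = c("cancer", "healthy"),
                              predicted = c("cancer", "healthy")))
  print(m)
  invisible(x)
}

#' Evaluate a fitted classifier on labeled rows
#'
#' @param model An `fp_classifier`.
#' @param data A `labeled_dataset` (non-empty, `F18` set).
#' @return A [confusion_matrix()] whose counts sum to the number of rows.
#' @export
evaluate_model <- function(model, data) {
  feats <- if (inherits(data, "labeled_dataset")) data$features else data
  if (nrow(feats) == 0L) stop("no rows to evaluate", call. = FALSE)
  truth <- as.integer(feats$F18)
  pred <- predict(model, data, type = "class")
  confusion_matrix(TP = sum(pred == 1L & truth == 1L),
                   FP = sum(pred == 1L & truth == 0L),
                   FN = sum(pred == 0L & truth == 1L),
                   TN = sum(pred == 0L & truth == 0L))
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+FP+TN+FN), precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R). A zero denominator yields `NA` with a
#' warning rather than a silent zero.
#'
#' @param cm A [confusion_matrix()] with positive total.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classifier_metrics <- function(cm) {
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      NA_real_
    } else num / den
  }
  precision <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  recall <- safe_div(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    warning("F1 undefined: zero denominator", call. = FALSE)
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  c(accuracy = (cm$TP + cm$TN) / total,
    precision = precision, recall = recall, f1 = f1)
}

#' Cross-validated training and held-out evaluation
#'
#' The package's central fitting routine. For every classifier spec it runs
#' stratified k-fold cross-validation on the training rows (each fold model
#' is trained on the other k-1 folds and scored both on its held-out fold
#' and on its own training rows), then refits on all training rows and
#' scores that final model on the held-out validation set. Wall-clock
#' training and prediction times are recorded for information only.
#'
#' @param train Training `labeled_dataset`.
#' @param plan A [stratified_kfold()] plan over `train`.
#' @param specs List of [classifier_spec()] objects (a single spec is
#'   accepted).
#' @param validation Held-out `labeled_dataset`.
#' @param fold_score Which per-fold score the summary reports:
#'   `"holdout"` (default, score on the held-out fold) or `"train"` (score
#'   on the fold model's own training rows). Both are always stored.
#' @return An object of class `fp_experiment`: per classifier a list of
#'   fold results (`confusion`, `metrics`, `confusion_train`,
#'   `metrics_train`, timings), the validation result, and the final fitted
#'   model.
#' @seealso [summary.fp_experiment()], [write_report()]
#' @export
run_experiment <- function(train, plan, specs, validation,
                           fold_score = c("holdout", "train")) {
  fold_score <- match.arg(fold_score)
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (!inherits(plan, "fold_plan") || length(plan$fold) != nrow(train$features)) {
    stop("`plan` is not a fold plan consistent with `train`", call. = FALSE)
  }
  results <- lapply(specs, function(spec) {
    folds <- lapply(seq_len(plan$k), function(i) {
      hold <- plan$fold == i
      t0 <- proc.time()[["elapsed"]]
      model <- fit_classifier(spec, subset_dataset(train, !hold))
      t1 <- proc.time()[["elapsed"]]
      cm_hold <- evaluate_model(model, subset_dataset(train, hold))
      cm_train <- evaluate_model(model, subset_dataset(train, !hold))
      t2 <- proc.time()[["elapsed"]]
      list(fold = i,
           confusion = cm_hold, metrics = classifier_metrics(cm_hold),
           confusion_train = cm_train,
           metrics_train = classifier_metrics(cm_train),
           train_time = t1 - t0, predict_time = t2 - t1)
    })
    t0 <- proc.time()[["elapsed"]]
    final <- fit_classifier(spec, train)
    t1 <- proc.time()[["elapsed"]]
    cm_val <- evaluate_model(final, validation)
    list(spec = spec, folds = folds, model = final,
         validation = list(confusion = cm_val,
                           metrics = classifier_metrics(cm_val),
                           train_time = t1 - t0))
  })
  names(results) <- vapply(specs, function(s) s$family, "")
  structure(list(classifiers = results, k = plan$k,
                 fold_score = fold_score,
                 n_train = nrow(train$features),
                 n_validation = nrow(validation$features)),
            class = "fp_experiment")
}

#' Flatten an experiment into a results table
#'
#' One row per classifier/fold plus one validation row per classifier, with
#' columns Classifier, Fold, Accuracy, Precision, Recall, F1.
#'
#' @param x An `fp_experiment`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @export
as.data.frame.fp_experiment <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rows <- list()
  for (res in x$classifiers) {
    for (fr in res$folds) {
      met <- if (x$fold_score == "holdout") fr$metrics else fr$metrics_train
      rows[[length(rows) + 1L]] <- data.frame(
        Classifier = res$spec$family, Fold = as.character(fr$fold),
        Accuracy = met[["accuracy"]], Precision = met[["precision"]],
        Recall = met[["recall"]], F1 = met[["f1"]])
    }
    met <- res$validation$metrics
    rows[[length(rows) + 1L]] <- data.frame(
      Classifier = res$spec$family, Fold = "validation",
      Accuracy = met[["accuracy"]], Precision = met[["precision"]],
      Recall = met[["recall"]], F1 = met[["f1"]])
  }
  do.call(rbind, rows)
}

#' @export
print.fp_experiment <- function(x, ...) {
  cat(sprintf(
    "Screening experiment: %d classifier(s), %d-fold CV on %d rows, %d validation rows\n",
    length(x$classifiers), x$k, x$n_train, x$n_validation))
  cat(sprintf("Per-fold scores: %s fold\n\n",
              if (x$fold_score == "holdout") "held-out" else "training"))
  df <- as.data.frame(x)
  df[c("Accuracy", "Precision", "Recall", "F1")] <-
    lapply(df[c("Accuracy", "Precision", "Recall", "F1")],
           function(v) round(v, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarise a screening experiment
#'
#' @param object An `fp_experiment`.
#' @param ... Unused.
#' @return Invisibly, the flat results table.
#' @export
summary.fp_experiment <- function(object, ...) {
  print(object)
  df <- as.data.frame(object)
  val <- df[df$Fold == "validation", ]
  best <- val[which.max(val$Accuracy), ]
  cat(sprintf("\nBest validation accuracy: %.2f (%s)\n",
              best$Accuracy, best$Classifier))
  invisible(df)
}
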