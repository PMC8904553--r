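test_that("classifier specs carry the study hyperparameters and reject unknowns", {
  rf <- classifier_spec("random-forest")
  expect_equal(rf$hyperparameters$n_estimators, 100L)
  expect_equal(rf$hyperparameters$criterion, "gini")
  expect_equal(rf$hyperparameters$min_samples_split, 2L)
  expect_equal(rf$hyperparameters$min_samples_leaf, 1L)
  xgb <- classifier_spec("gradient-boosted-trees")
  expect_equal(xgb$hyperparameters$booster, "gbtree")
  expect_equal(xgb$hyperparameters$learning_rate, 0.3)
  expect_equal(xgb$hyperparameters$min_split_loss, 0)
  expect_equal(xgb$hyperparameters$max_depth, 6L)
  nb <- classifier_spec("gaussian-naive-bayes")
  expect_null(nb$hyperparameters$priors)
  expect_equal(nb$hyperparameters$var_smoothing, 1e-9)
  nn <- classifier_spec("neural-net")
  expect_equal(nn$hyperparameters$units, c(32L, 16L, 1L))
  expect_equal(nn$hyperparameters$epochs, 200L)
  expect_error(classifier_spec("random-forest", list(bogus = 1)), "unknown")
})

test_that("metrics follow their defining formulas", {
  cm <- confusion_matrix(TP = 50, FP = 5, FN = 10, TN = 35)
  met <- classifier_metrics(cm)
  expect_equal(unname(met["accuracy"]), 0.85)
  expect_equal(unname(met["precision"]), 50 / 55, tolerance = 1e-6)
  expect_equal(unname(met["recall"]), 50 / 60, tolerance = 1e-6)
  expect_equal(unname(met["f1"]), 0.8696, tolerance = 1e-4)

  perfect <- classifier_metrics(confusion_matrix(40, 0, 0, 30))
  expect_equal(unname(perfect), rep(1, 4))

  # swapping FP and FN preserves accuracy, swaps precision and recall
  sw <- classifier_metrics(confusion_matrix(TP = 50, FP = 10, FN = 5, TN = 35))
  expect_equal(sw[["accuracy"]], met[["accuracy"]])
  expect_equal(sw[["precision"]], met[["recall"]])
  expect_equal(sw[["recall"]], met[["precision"]])
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(31)
  for (i in 1:25) {
    cm <- confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    met <- classifier_metrics(cm)
    p <- met[["precision"]]; r <- met[["recall"]]
    expect_equal(met[["f1"]], 2 * p * r / (p + r), tolerance = 1e-12)
    expect_true(met[["f1"]] >= min(p, r) - 1e-12 &&
                  met[["f1"]] <= max(p, r) + 1e-12)
    expect_true(all(met >= 0 & met <= 1))
  }
})

test_that("undefined metrics surface as NA with a warning, never silent zero", {
  # no positive predictions: precision denominator is zero
  cm <- confusion_matrix(TP = 0, FP = 0, FN = 10, TN = 30)
  expect_warning(met <- classifier_metrics(cm), "precision")
  expect_true(is.na(met[["precision"]]))
  expect_equal(met[["accuracy"]], 0.75)
})

test_that("evaluation counts follow the cancer-positive orientation", {
  ds <- toy_dataset(n_per_class = 10L)
  model <- fit_classifier(classifier_spec("gaussian-naive-bayes"), ds)
  cm <- evaluate_model(model, ds)
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 20L)

  # constant "sick" predictor on a 30 healthy / 40 sick set
  truth <- c(rep(0L, 30), rep(1L, 40))
  pred <- rep(1L, 70)
  cm2 <- confusion_matrix(TP = sum(pred == 1 & truth == 1),
                          FP = sum(pred == 1 & truth == 0),
                          FN = sum(pred == 0 & truth == 1),
                          TN = sum(pred == 0 & truth == 0))
  expect_equal(unlist(cm2[c("TP", "FP", "FN", "TN")]),
               c(TP = 40L, FP = 30L, FN = 0L, TN = 0L))
})

test_that("all four families separate unit-separated point clouds", {
  ds <- toy_dataset(n_per_class = 15L, gap = 5)
  for (fam in c(classical_families, "neural-net")) {
    model <- fit_classifier(classifier_spec(fam, seed = 2), ds)
    cm <- evaluate_model(model, ds)
    acc <- classifier_metrics(cm)[["accuracy"]]
    expect_equal(acc, 1, info = fam,
                 tolerance = if (fam == "neural-net") 0.1 else 1e-12)
  }
  expect_error(fit_classifier(classifier_spec("random-forest"),
                              subset_ds <- {
                                d <- toy_dataset(); d$features <- d$features[d$features$F18 == 1, ]; d
                              }),
               "single class")
})

test_that("naive Bayes decisions are invariant under dataset duplication", {
  ds <- toy_dataset(n_per_class = 12L, gap = 2, noise = 0.8)
  dup <- ds
  dup$features <- rbind(ds$features, ds$features)
  m1 <- fit_classifier(classifier_spec("gaussian-naive-bayes"), ds)
  m2 <- fit_classifier(classifier_spec("gaussian-naive-bayes"), dup)
  expect_identical(predict(m1, ds), predict(m2, ds))
})

test_that("tree and Bayes fits are seed-deterministic", {
  ds <- toy_dataset(n_per_class = 12L, gap = 1, noise = 1)
  for (fam in classical_families) {
    p1 <- predict(fit_classifier(classifier_spec(fam, seed = 7), ds), ds,
                  type = "prob")
    p2 <- predict(fit_classifier(classifier_spec(fam, seed = 7), ds), ds,
                  type = "prob")
    expect_identical(p1, p2, info = fam)
  }
})

test_that("prediction rejects feature-dimension mismatches", {
  ds <- toy_dataset()
  model <- fit_classifier(classifier_spec("random-forest"), ds)
  bad <- ds$features[paste0("F", 1:10)]
  expect_error(predict(model, bad), "mismatch")
})

test_that("experiments report k folds plus validation per classifier", {
  spectra <- generate_fixtures(seed = 5, scale = "small")
  panel <- liquid_panel(label_indices = seq(1.30, 1.50, 0.05),
                        replicates = 6L)
  model <- small_model()
  ds <- build_dataset(extract_feature_table(
    generate_study_design(panel, model, seed = 5), model))
  sp <- split_validation(ds, 0.2, seed = 3)
  plan <- stratified_kfold(sp$train, 3L, seed = 3)
  specs <- lapply(c("random-forest", "gaussian-naive-bayes"),
                  classifier_spec, seed = 11)
  exp1 <- run_experiment(sp$train, plan, specs, sp$validation)
  df <- as.data.frame(exp1)
  expect_equal(nrow(df), 2L * (3L + 1L))
  expect_equal(sum(df$Fold == "validation"), 2L)
  # every metric is recomputable from its stored confusion matrix
  for (res in exp1$classifiers) {
    for (fr in res$folds) {
      expect_equal(fr$metrics, classifier_metrics(fr$confusion))
      total <- with(fr$confusion, TP + FP + FN + TN)
      expect_equal(total, sum(plan$fold == fr$fold))
    }
    expect_equal(res$validation$metrics,
                 classifier_metrics(res$validation$confusion))
  }
  # identical seeds reproduce the tree/Bayes report exactly
  exp2 <- run_experiment(sp$train, plan, specs, sp$validation)
  expect_identical(as.data.frame(exp1), as.data.frame(exp2))
})
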