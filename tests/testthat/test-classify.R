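# Classifier bench: folds, training, metrics, CV, importances, grid search,
# ROC curves.

test_that("stratified folds partition the data with balanced classes", {
  # 80 samples, 8 balanced classes, k = 10: one test sample per class per fold
  tab <- tibble::tibble(variety = rep(LETTERS[1:8], each = 10),
                        f1 = rnorm(80))
  folds <- stratified_kfold(tab, k = 10, seed = 4)
  for (f in folds) {
    expect_length(f$test, 8)
    expect_equal(sort(tab$variety[f$test]), LETTERS[1:8])
    expect_setequal(c(f$train, f$test), 1:80)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), 1:80)
  expect_equal(sum(lengths(lapply(folds, `[[`, "test"))), 80)

  # unbalanced random labels: per-fold class counts within +-1 of fair share
  set.seed(19)
  for (i in 1:3) {
    y <- sample(c("A", "B", "C"), 60, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
    y <- c(y, rep(c("A", "B", "C"), 4))  # guarantee >= k members
    tab2 <- tibble::tibble(variety = y, f1 = seq_along(y))
    k <- 4
    folds2 <- stratified_kfold(tab2, k = k, seed = i)
    for (cl in c("A", "B", "C")) {
      per_fold <- vapply(folds2, function(f) sum(tab2$variety[f$test] == cl),
                         numeric(1))
      fair <- sum(tab2$variety == cl) / k
      expect_true(all(abs(per_fold - fair) <= 1))
    }
  }

  # determinism and the small-class guard
  expect_identical(stratified_kfold(tab, k = 10, seed = 4), folds)
  expect_error(stratified_kfold(tab, k = 11, seed = 1),
               class = "grainscan_stratification_error")
})

test_that("evaluation metrics satisfy the confusion-matrix identities", {
  # perfect predictions
  ev <- evaluate_predictions(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(ev$accuracy, 1)
  expect_true(all(ev$per_class$f1 == 1))

  # the harmonic-mean identity on printed-precision inputs
  expect_equal(round(f1_score(0.949, 0.888), 3), 0.917)

  # random confusion vs literal per-class counting
  set.seed(23)
  lv <- c("A", "B", "C", "D")
  truth <- sample(lv, 120, replace = TRUE)
  pred <- ifelse(runif(120) < 0.6, truth, sample(lv, 120, replace = TRUE))
  ev2 <- evaluate_predictions(truth, pred, levels = lv)
  for (ci in seq_along(lv)) {
    cl <- lv[ci]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    P <- if (tp + fp > 0) tp / (tp + fp) else 0
    R <- if (tp + fn > 0) tp / (tp + fn) else 0
    expect_equal(ev2$per_class$precision[ci], P)
    expect_equal(ev2$per_class$recall[ci], R)
    expect_equal(ev2$per_class$f1[ci],
                 if (P + R > 0) 2 * P * R / (P + R) else 0)
  }
  expect_equal(ev2$accuracy, mean(truth == pred))
  expect_equal(ev2$accuracy, sum(diag(ev2$confusion)) / sum(ev2$confusion))
  expect_equal(ev2$macro_f1, mean(ev2$per_class$f1))
  expect_equal(unname(rowSums(ev2$confusion)),
               unname(as.vector(table(factor(truth, lv)))))
  expect_equal(glance(ev2)$macro_f1, ev2$macro_f1)
  expect_equal(nrow(tidy(ev2)), 4)
})

test_that("training is seeded, separable data is learnt, degenerate data errors", {
  tab <- toy_two_class_table(20, gap = 8, seed = 2)
  for (m in c("dt", "rf")) {
    fit <- train_classifier(tab, model = m, seed = 3)
    expect_equal(evaluate_model(fit, tab)$accuracy, 1)
  }
  # stochastic models are reproducible given the seed
  f1 <- train_classifier(tab, model = "rf", seed = 5)
  f2 <- train_classifier(tab, model = "rf", seed = 5)
  expect_identical(predict(f1, tab, type = "prob"),
                   predict(f2, tab, type = "prob"))

  single <- dplyr::filter(tab, .data$variety == "A")
  expect_error(train_classifier(single, model = "rf"),
               class = "grainscan_degenerate_training")
})

test_that("every bench model learns well-separated classes", {
  tab <- toy_two_class_table(24, gap = 8, seed = 6)
  folds <- stratified_kfold(tab, k = 3, seed = 1)
  for (m in model_kinds()) {
    fit <- train_classifier(tab[folds[[1]]$train, ], model = m, seed = 2)
    acc <- evaluate_model(fit, tab[folds[[1]]$test, ])$accuracy
    if (m == "svm_sigmoid") expect_gte(acc, 0.5) else expect_gte(acc, 0.9)
    pr <- predict(fit, tab[folds[[1]]$test, ], type = "prob")
    expect_equal(dim(pr), c(length(folds[[1]]$test), 2))
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
  }
})

test_that("cross-validation aggregates fold metrics and is deterministic", {
  tab <- toy_two_class_table(15, gap = 8, seed = 7)
  cv <- cross_validate(tab, model = "dt", k = 3, seed = 9)
  expect_length(cv$fold_reports, 3)
  expect_equal(cv$mean_accuracy, mean(cv$summary$accuracy))
  expect_equal(cv$min_accuracy, min(cv$summary$accuracy))
  expect_equal(cv$max_accuracy, max(cv$summary$accuracy))
  cv2 <- cross_validate(tab, model = "dt", k = 3, seed = 9)
  expect_equal(cv$summary, cv2$summary)
  expect_equal(glance(cv)$mean_macro_f1, cv$mean_macro_f1)
})

test_that("feature importances rank the signal feature first", {
  set.seed(13)
  n <- 60
  tab <- tibble::tibble(
    variety = rep(c("A", "B"), each = n / 2),
    signal = c(rnorm(n / 2, 0), rnorm(n / 2, 10)),
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)
  )
  fit <- train_classifier(tab, model = "rf", seed = 1)
  rk <- rank_and_select_features(fit, tab, top_n = 2)
  expect_equal(rk$ranking$feature[1], "signal")
  expect_equal(sum(rk$ranking$importance), 1)
  expect_true(all(rk$ranking$importance >= 0))
  expect_length(rk$selected, 2)
  expect_named(rk$reduced, c("variety", rk$selected), ignore.order = TRUE)

  # top_n = N keeps everything; non-tree models are refused
  rk_all <- rank_and_select_features(fit, tab, top_n = 4)
  expect_length(rk_all$selected, 4)
  lr_fit <- train_classifier(tab, model = "lr", seed = 1)
  expect_error(rank_and_select_features(lr_fit, tab),
               class = "grainscan_unsupported_model")
})

test_that("the default importance cut reduces a full table to 59 features", {
  regions <- lapply(1:16, function(i)
    ellipse_region(25 + i, 13, angle = 0.3 * i, label = i, seed = i))
  tab <- build_feature_table(regions, labels = rep(c("L", "S"), 8))
  fit <- train_classifier(tab, model = "rf", seed = 2)
  rk <- rank_and_select_features(fit, tab)
  expect_length(rk$selected, 59)
  expect_equal(ncol(rk$reduced), 3 + 59)
  expect_equal(rk$reduced$grain_id, tab$grain_id)  # row order preserved
})

test_that("grid search enumerates the product and recovers the better spec", {
  tab <- toy_two_class_table(15, gap = 8, seed = 3)
  g1 <- grid_search(tab, model = "dt", grid = list(cp = 0.01), k = 3, seed = 1)
  expect_equal(g1$best_hyper$cp, 0.01)
  expect_equal(nrow(g1$scores), 1)

  g2 <- grid_search(tab, model = "dt",
                    grid = list(cp = c(2, 0.01), minsplit = c(5, 10)),
                    k = 3, seed = 1)
  expect_equal(nrow(g2$scores), 4)
  expect_equal(g2$best_hyper$cp, 0.01)  # cp = 2 cannot split at all
  expect_equal(g2$best_score, max(g2$scores$mean_macro_f1))

  expect_error(grid_search(tab, model = "dt", grid = list(), k = 3),
               class = "grainscan_invalid_input")
})

test_that("ROC curves hit the perfect, chance and Mann-Whitney anchors", {
  truth <- c(rep("A", 6), rep("B", 6))
  perfect <- cbind(A = c(rep(0.9, 6), rep(0.1, 6)),
                   B = c(rep(0.1, 6), rep(0.9, 6)))
  roc <- roc_one_vs_rest(truth, perfect)
  expect_equal(roc$auc$auc, c(1, 1))

  flat <- cbind(A = rep(0.5, 12), B = rep(0.5, 12))
  roc_flat <- roc_one_vs_rest(truth, flat)
  expect_equal(roc_flat$auc$auc, c(0.5, 0.5))

  set.seed(29)
  sc <- cbind(A = runif(12), B = runif(12))
  roc_r <- roc_one_vs_rest(truth, sc)
  expect_equal(roc_r$auc$auc[roc_r$auc$class == "A"],
               oracle_auc(sc[truth == "A", "A"], sc[truth != "A", "A"]))
  # curves are monotone and span (0,0) to (1,1)
  for (cl in c("A", "B")) {
    p <- dplyr::filter(roc_r$points, .data$class == cl)
    expect_true(all(diff(p$fpr) >= 0))
    expect_true(all(diff(p$tpr) >= 0))
    expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
    expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
  }

  # a class absent from the test set is flagged, not an error
  roc_abs <- roc_one_vs_rest(rep("A", 5),
                             cbind(A = runif(5), B = runif(5)))
  expect_false(roc_abs$auc$defined[roc_abs$auc$class == "B"])
})

test_that("cross-checks against pROC agree on model scores", {
  tab <- toy_two_class_table(18, gap = 4, seed = 8)
  folds <- stratified_kfold(tab, k = 3, seed = 2)
  fit <- train_classifier(tab[folds[[1]]$train, ], model = "rf", seed = 2)
  test <- tab[folds[[1]]$test, ]
  sc <- predict(fit, test, type = "prob")
  ours <- roc_one_vs_rest(test$variety, sc)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = test$variety == "A", predictor = sc[, "A"], quiet = TRUE)))
  expect_equal(ours$auc$auc[ours$auc$class == "A"], as.numeric(ref),
               tolerance = 1e-12)
})
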