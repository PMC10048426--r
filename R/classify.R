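# Classifier bench: eight model kinds trained on feature tables, evaluated
# under stratified k-fold cross-validation with confusion-matrix metrics,
# one-vs-rest ROC curves, feature-importance selection and grid search.

#' Model kinds supported by the bench
#' @return Character vector of the eight model codes.
#' @export
model_kinds <- function() {
  c("lr", "dt", "rf", "mlp", "svm_linear", "svm_poly", "svm_rbf",
    "svm_sigmoid")
}

#' Stratified k-fold split
#'
#' Shuffles within each class (deterministically given `seed`) and deals
#' samples round-robin to folds, so per-fold class counts differ from the
#' balanced allocation by at most one sample.
#'
#' @param table Feature table with a label column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return List of `k` lists with integer `train` and `test` row indices.
#' @export
stratified_kfold <- function(table, k = 10L, seed = 1L, label_col = "variety") {
  y <- table[[label_col]]
  n <- length(y)
  if (k < 2L || k > n) {
    abort_grainscan("k must lie in [2, nrow(table)]", "grainscan_invalid_input")
  }
  tab <- table(y)
  if (any(tab < k)) {
    abort_grainscan(
      sprintf("class(es) with fewer than k samples: %s",
              paste(names(tab)[tab < k], collapse = ", ")),
      "grainscan_stratification_error"
    )
  }
  set.seed(seed)
  fold_of <- integer(n)
  for (cl in names(tab)) {
    ids <- which(y == cl)
    ids <- ids[sample.int(length(ids))]
    fold_of[ids] <- rep_len(seq_len(k), length(ids))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

default_hyper <- function(kind) {
  switch(kind,
    lr = list(decay = 1e-4, maxit = 200),
    dt = list(cp = 0.01, minsplit = 5),
    rf = list(n_trees = 200, max_depth = Inf, min_samples_split = 2,
              min_samples_leaf = 1),
    mlp = list(size = 8, decay = 1e-3, maxit = 150),
    list(cost = 1, gamma = NULL, degree = 3, coef0 = 1)  # svm kernels
  )
}

#' Train one classifier
#'
#' Fits one of the eight bench models on a labelled feature table. Features
#' are standardised internally for the scale-sensitive models (LR, MLP and
#' the SVM kernels; zero-variance columns are left unscaled); tree models
#' see raw features. All
#' stochastic fits are seeded, so identical data + spec + seed give
#' identical models.
#'
#' @param table Feature table (provenance columns `scene`/`grain_id` are
#'   ignored).
#' @param model One of [model_kinds()].
#' @param hyper Named list of hyperparameters; unset entries take defaults.
#'   For `"rf"`: `n_trees`, `max_depth` (mapped to a maximum node count),
#'   `min_samples_split` and `min_samples_leaf` (both mapped to the minimum
#'   node size).
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return A `grain_classifier` object.
#' @export
train_classifier <- function(table, model = "rf", hyper = list(), seed = 1L,
                             label_col = "variety") {
  model <- match.arg(model, model_kinds())
  y <- factor(table[[label_col]])
  if (nlevels(y) < 2L) {
    abort_grainscan("training data holds a single class",
                    "grainscan_degenerate_training")
  }
  feats <- setdiff(names(table), c(meta_cols(), label_col))
  X <- as.matrix(table[, feats, drop = FALSE])
  if (any(!is.finite(X))) {
    abort_grainscan("non-finite feature values", "grainscan_invalid_input")
  }
  hp <- utils::modifyList(default_hyper(model), hyper)
  set.seed(seed)

  center <- scale_ <- NULL
  if (!model %in% c("dt", "rf")) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }

  fit <- switch(model,
    lr = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, trace = FALSE,
                     MaxNWts = 1e5, maxit = hp$maxit, decay = hp$decay)
    },
    dt = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit))
    },
    rf = {
      maxnodes <- if (is.finite(hp$max_depth)) min(2^hp$max_depth, nrow(X))
                  else NULL
      nodesize <- max(hp$min_samples_leaf, ceiling(hp$min_samples_split / 2))
      randomForest::randomForest(
        x = X, y = y, ntree = hp$n_trees, nodesize = nodesize,
        maxnodes = maxnodes, importance = FALSE
      )
    },
    mlp = {
      nnet::nnet(x = X, y = nnet::class.ind(y), size = hp$size,
                 softmax = TRUE, decay = hp$decay, maxit = hp$maxit,
                 MaxNWts = 1e6, trace = FALSE)
    },
    {
      kernel <- switch(model, svm_linear = "linear", svm_poly = "polynomial",
                       svm_rbf = "radial", svm_sigmoid = "sigmoid")
      args <- list(x = X, y = y, kernel = kernel, probability = TRUE,
                   cost = hp$cost, scale = FALSE)
      if (!is.null(hp$gamma)) args$gamma <- hp$gamma
      if (kernel %in% c("polynomial", "sigmoid")) args$coef0 <- hp$coef0
      if (kernel == "polynomial") args$degree <- hp$degree
      do.call(e1071::svm, args)
    }
  )
  structure(
    list(fit = fit, kind = model, levels = levels(y), features = feats,
         center = center, scale = scale_, hyper = hp, seed = seed,
         label_col = label_col),
    class = "grain_classifier"
  )
}

#' @export
print.grain_classifier <- function(x, ...) {
  cat(sprintf("grain_classifier: %s, %d classes, %d features\n",
              x$kind, length(x$levels), length(x$features)))
  invisible(x)
}

#' Predict classes or class probabilities
#'
#' @param object A `grain_classifier`.
#' @param newdata Feature table (must contain the training feature columns).
#' @param type `"class"` or `"prob"`.
#' @param ... Ignored.
#' @return Factor of predicted classes, or a numeric matrix of per-class
#'   scores with one column per training class. Ties in the class vote go to
#'   the first class in registry (training-level) order.
#' @export
predict.grain_classifier <- function(object, newdata, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  }
  lv <- object$levels
  prob <- switch(object$kind,
    lr = {
      p <- predict(object$fit, data.frame(X, check.names = FALSE),
                   type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p, deparse.level = 0)
      colnames(p) <- if (ncol(p) == length(lv)) lv else colnames(p)
      p
    },
    dt = predict(object$fit, data.frame(X, check.names = FALSE),
                 type = "prob"),
    rf = predict(object$fit, X, type = "prob"),
    mlp = {
      p <- predict(object$fit, X)
      colnames(p) <- colnames(object$fit$fitted.values)
      p
    },
    {
      pr <- predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")
    }
  )
  prob <- prob[, lv, drop = FALSE]
  if (type == "prob") return(prob)
  factor(lv[apply(prob, 1, which.max)], levels = lv)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`, 0 when both are 0. Vectorised.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Confusion-matrix metrics from truth and predictions
#'
#' Precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and their harmonic
#' mean F1 per class, plus accuracy and macro (unweighted) and weighted
#' averages. A class never predicted gets precision 0 by convention.
#'
#' @param truth,pred Factors or character vectors of equal length.
#' @param levels Class levels fixing the confusion-matrix order.
#' @return A `grain_eval` object.
#' @export
evaluate_predictions <- function(truth, pred,
                                 levels = sort(unique(c(as.character(truth),
                                                        as.character(pred))))) {
  if (length(truth) == 0L) {
    abort_grainscan("empty test set", "grainscan_invalid_input")
  }
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- f1_score(precision, recall)
  per_class <- tibble(
    class = levels, support = as.integer(support),
    precision = as.numeric(precision), recall = as.numeric(recall),
    f1 = as.numeric(f1)
  )
  w <- support / sum(support)
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      accuracy = sum(tp) / sum(cm),
      macro_precision = mean(precision), macro_recall = mean(recall),
      macro_f1 = mean(f1),
      weighted_precision = sum(w * precision),
      weighted_recall = sum(w * recall),
      weighted_f1 = sum(w * f1)
    ),
    class = "grain_eval"
  )
}

#' Evaluate a fitted classifier on a test table
#'
#' @param model A `grain_classifier`.
#' @param test_table Labelled feature table.
#' @return A `grain_eval` object.
#' @export
evaluate_model <- function(model, test_table) {
  if (nrow(test_table) == 0L) {
    abort_grainscan("empty test set", "grainscan_invalid_input")
  }
  pred <- predict(model, test_table, type = "class")
  evaluate_predictions(test_table[[model$label_col]], pred,
                       levels = model$levels)
}

#' @export
print.grain_eval <- function(x, ...) {
  cat(sprintf("accuracy %.3f | macro P %.3f R %.3f F1 %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x A `grain_eval`.
#' @param ... Ignored.
#' @export
tidy.grain_eval <- function(x, ...) x$per_class

#' @rdname evaluate_predictions
#' @export
glance.grain_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
         macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
         weighted_f1 = x$weighted_f1)
}

#' Heatmap of a confusion matrix
#' @param object A `grain_eval`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.grain_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "actual", fill = "count")
}

#' Cross-validate a model spec
#'
#' Stratified k-fold cross-validation; per-fold reports plus the mean,
#' minimum and maximum of accuracy and macro F1.
#'
#' @inheritParams train_classifier
#' @param k Number of folds.
#' @return A `grain_cv` object with `fold_reports`, `summary` (per-fold
#'   tibble) and aggregate fields.
#' @export
cross_validate <- function(table, model = "rf", k = 10L, hyper = list(),
                           seed = 1L, label_col = "variety") {
  folds <- stratified_kfold(table, k = k, seed = seed, label_col = label_col)
  reports <- lapply(seq_along(folds), function(i) {
    fit <- train_classifier(table[folds[[i]]$train, ], model = model,
                            hyper = hyper, seed = seed + i,
                            label_col = label_col)
    evaluate_model(fit, table[folds[[i]]$test, ])
  })
  summary <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    tibble(fold = i, accuracy = reports[[i]]$accuracy,
           macro_f1 = reports[[i]]$macro_f1)
  }))
  structure(
    list(model = model, k = k, seed = seed,
         fold_reports = reports, summary = summary,
         mean_accuracy = mean(summary$accuracy),
         min_accuracy = min(summary$accuracy),
         max_accuracy = max(summary$accuracy),
         mean_macro_f1 = mean(summary$macro_f1)),
    class = "grain_cv"
  )
}

#' @export
print.grain_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV (%s): mean accuracy %.3f [%.3f, %.3f], mean macro F1 %.3f\n",
    x$k, x$model, x$mean_accuracy, x$min_accuracy, x$max_accuracy,
    x$mean_macro_f1))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `grain_cv`.
#' @param ... Ignored.
#' @export
tidy.grain_cv <- function(x, ...) x$summary

#' @rdname cross_validate
#' @export
glance.grain_cv <- function(x, ...) {
  tibble(model = x$model, k = x$k, mean_accuracy = x$mean_accuracy,
         min_accuracy = x$min_accuracy, max_accuracy = x$max_accuracy,
         mean_macro_f1 = x$mean_macro_f1)
}

#' Rank features by tree importance and select the top block
#'
#' Importances are taken from a random-forest (mean Gini decrease) or
#' decision-tree fit, normalised to sum to 1, and the top `top_n` features
#' (or those above `threshold`) are selected; ties break by feature-registry
#' order so selection is reproducible.
#'
#' @param model A `grain_classifier` of kind `"rf"` or `"dt"`, fitted with
#'   importances available.
#' @param table Feature table to reduce.
#' @param top_n Number of features to keep (default 59).
#' @param threshold Alternative to `top_n`: keep features with normalised
#'   importance above this value.
#' @return List: `ranking` (tibble feature/importance/selected), `selected`
#'   (names), `reduced` (the table restricted to provenance + label +
#'   selected features, row order preserved).
#' @export
rank_and_select_features <- function(model, table, top_n = 59L,
                                     threshold = NULL) {
  if (!model$kind %in% c("rf", "dt")) {
    abort_grainscan("feature importances need a tree-based model (rf, dt)",
                    "grainscan_unsupported_model")
  }
  imp_raw <- if (model$kind == "rf") {
    v <- model$fit$importance[, "MeanDecreaseGini"]
    setNames(as.numeric(v), rownames(model$fit$importance))
  } else {
    v <- model$fit$variable.importance
    if (is.null(v)) v <- setNames(numeric(0), character(0))
    setNames(as.numeric(v), names(v))
  }
  imp <- setNames(numeric(length(model$features)), model$features)
  imp[names(imp_raw)[names(imp_raw) %in% names(imp)]] <-
    imp_raw[names(imp_raw) %in% names(imp)]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp)  # stable: ties keep registry order
  ranked <- imp[ord]
  selected <- if (!is.null(threshold)) {
    names(ranked)[ranked > threshold]
  } else {
    names(ranked)[seq_len(min(top_n, length(ranked)))]
  }
  ranking <- tibble(feature = names(ranked), importance = as.numeric(ranked),
                    selected = names(ranked) %in% selected)
  keep_cols <- c(intersect(c(meta_cols(), model$label_col), names(table)),
                 selected)
  list(ranking = ranking, selected = selected,
       reduced = table[, unique(keep_cols), drop = FALSE])
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates the full Cartesian product of the grid axes by k-fold
#' cross-validated mean macro F1; ties go to the first combination in grid
#' order.
#'
#' @inheritParams cross_validate
#' @param grid Named list of hyperparameter value vectors.
#' @return List: `best_hyper`, `best_score`, `scores` (tibble with one row
#'   per combination).
#' @export
grid_search <- function(table, model = "rf", grid, k = 5L, seed = 1L,
                        label_col = "variety") {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    abort_grainscan("grid must be a non-empty named list of value vectors",
                    "grainscan_invalid_input")
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    hp <- as.list(combos[i, , drop = FALSE])
    cv <- cross_validate(table, model = model, k = k, hyper = hp,
                         seed = seed, label_col = label_col)
    cv$mean_macro_f1
  }, numeric(1))
  best <- which.max(scores)  # first maximiser
  list(
    best_hyper = as.list(combos[best, , drop = FALSE]),
    best_score = scores[best],
    scores = dplyr::bind_cols(as_tibble(combos),
                              tibble(mean_macro_f1 = scores))
  )
}

#' One-vs-rest ROC curves
#'
#' For each class, sweeps a threshold over that class's scores (the class is
#' positive, all others negative), recording the false- and true-positive
#' rates, and integrates the area under the curve by the trapezoid rule
#' (with ties handled so the AUC equals the Mann-Whitney statistic).
#'
#' @param truth Factor/character of true classes.
#' @param scores Numeric matrix, one column per class.
#' @param levels Class order; defaults to the score columns.
#' @return A `grain_roc` object: `points` tibble (class, threshold, fpr,
#'   tpr) and `auc` tibble (class, auc, defined).
#' @export
roc_one_vs_rest <- function(truth, scores,
                            levels = colnames(scores)) {
  truth <- as.character(truth)
  pts <- list(); aucs <- list()
  for (cl in levels) {
    pos <- truth == cl
    sc <- scores[, cl]
    if (!any(pos) || all(pos)) {
      aucs[[cl]] <- tibble(class = cl, auc = NA_real_, defined = FALSE)
      next
    }
    thr <- c(Inf, sort(unique(c(sc, 0, 1)), decreasing = TRUE), -Inf)
    tpr <- vapply(thr, function(t) mean(sc[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(sc[!pos] >= t), numeric(1))
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    pts[[cl]] <- tibble(class = cl, threshold = thr, fpr = fpr, tpr = tpr)
    aucs[[cl]] <- tibble(class = cl, auc = auc, defined = TRUE)
  }
  structure(
    list(points = dplyr::bind_rows(pts), auc = dplyr::bind_rows(aucs)),
    class = "grain_roc"
  )
}

#' ROC curves for a fitted model on a test table
#'
#' @param model A `grain_classifier`.
#' @param test_table Labelled feature table.
#' @return A `grain_roc`, see [roc_one_vs_rest()].
#' @export
roc_model <- function(model, test_table) {
  sc <- predict(model, test_table, type = "prob")
  roc_one_vs_rest(test_table[[model$label_col]], sc, levels = model$levels)
}

#' @export
print.grain_roc <- function(x, ...) {
  print(x$auc)
  invisible(x)
}

#' @rdname roc_one_vs_rest
#' @param x A `grain_roc`.
#' @param ... Ignored.
#' @export
tidy.grain_roc <- function(x, ...) x$points

#' @rdname roc_one_vs_rest
#' @param object A `grain_roc`.
#' @export
autoplot.grain_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate")
}
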