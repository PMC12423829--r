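#' Fit a bagged tree-ensemble activity classifier
#'
#' A random forest-style ensemble of CART trees (via \pkg{rpart}): each
#' tree is grown on a bootstrap sample of the training rows using a
#' random subset of `mtry` features, honoring the four standard
#' hyperparameters of tree ensembles: number of trees, maximum depth,
#' minimum samples to split a node and minimum samples per leaf. The
#' ensemble predicts the probability of class 1 as the mean of per-leaf
#' class-1 frequencies across trees, which is exactly the quantity the
#' tree-Shapley explainer decomposes.
#'
#' @param X numeric feature matrix or data.frame (rows = compounds).
#' @param y binary labels (0/1) with both classes present.
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param min_split minimum node size eligible for splitting.
#' @param min_leaf minimum samples per terminal node.
#' @param mtry features sampled per tree (default `floor(sqrt(p))`, at
#'   least 1).
#' @param seed RNG seed.
#' @return object of class `kmo_forest`.
#' @export
forest_fit <- function(X, y, n_trees = 50, max_depth = 8, min_split = 2,
                       min_leaf = 1, mtry = NULL, seed = 1L) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  set.seed(seed)
  # rpart caps tree depth at 30; deeper requests are indistinguishable at
  # these sample sizes, so the effective depth is clamped
  ctrl <- rpart::rpart.control(minsplit = min_split, minbucket = min_leaf,
                               maxdepth = min(max_depth, 30), cp = 0,
                               xval = 0,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  trees <- lapply(seq_len(n_trees), function(i) {
    # redraw bootstraps that lose a class entirely: the tree library
    # cannot grow a two-class tree from a single-class sample
    for (try in 1:100) {
      rows <- sample(nrow(X), replace = TRUE)
      if (length(unique(y[rows])) == 2) break
    }
    feats <- sort(sample(p, mtry))
    d <- X[rows, feats, drop = FALSE]
    d$.y <- factor(y[rows], levels = c(0, 1))
    fit <- rpart::rpart(.y ~ ., data = d, method = "class", control = ctrl)
    list(fit = fit, feats = names(X)[feats])
  })
  structure(list(trees = trees, feature_names = names(X),
                 hyperparameters = list(n_trees = n_trees,
                                        max_depth = max_depth,
                                        min_split = min_split,
                                        min_leaf = min_leaf, mtry = mtry),
                 n_train = nrow(X)),
            class = "kmo_forest")
}

#' Predict with a fitted ensemble
#'
#' @param object a `kmo_forest`.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param type `"prob"` for class-1 probability, `"class"` for the 0/1
#'   label at cutoff `cutoff`.
#' @param cutoff probability cutoff for class prediction (default 0.5).
#' @param ... unused.
#' @return numeric (prob) or integer (class) vector.
#' @export
predict.kmo_forest <- function(object, newdata, type = c("prob", "class"),
                               cutoff = 0.5, ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stop("newdata lacks model features: ", paste(missing, collapse = ", "))
  probs <- rowMeans(vapply(object$trees, function(t) {
    stats::predict(t$fit, newdata = newdata, type = "prob")[, "1"]
  }, numeric(nrow(newdata))))
  if (type == "prob") probs else as.integer(probs >= cutoff)
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fp,fn,tn confusion counts (positives = class 1).
#' @return list with accuracy, precision, recall, f1 and the counts.
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1, confusion = c(tp = tp, fp = fp, fn = fn, tn = tn), n = n)
}

#' Classification metrics from predictions and truth
#'
#' @param pred predicted 0/1 labels.
#' @param truth observed 0/1 labels.
#' @return see [metrics_from_confusion()].
#' @export
classification_metrics <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  metrics_from_confusion(tp = sum(pred == 1 & truth == 1),
                         fp = sum(pred == 1 & truth == 0),
                         fn = sum(pred == 0 & truth == 1),
                         tn = sum(pred == 0 & truth == 0))
}

# stratified k-fold assignment
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train the classifier with random hyperparameter search and k-fold CV
#'
#' Seeded random search over the standard tree-ensemble hyperparameter
#' box (trees 10-100, depth 2-32, min-split 2-16, min-leaf 1-16 by
#' default); each candidate is scored by mean stratified k-fold CV
#' accuracy, the best is refit on all training data, and the report
#' carries per-fold and aggregate metrics for the winning configuration.
#'
#' @param X training feature matrix/data.frame.
#' @param y binary 0/1 labels with both classes present.
#' @param search_space list of integer ranges `n_trees`, `max_depth`,
#'   `min_split`, `min_leaf` (each `c(lo, hi)`).
#' @param n_trials number of sampled configurations (default 30).
#' @param cv_folds folds for cross-validation (default 5).
#' @param seed RNG seed.
#' @return list with `model` (`kmo_forest`) and `report` (hyperparameters,
#'   cv_fold_metrics, cv_accuracy, training metrics).
#' @export
train_classifier <- function(X, y,
                             search_space = list(n_trees = c(10, 100),
                                                 max_depth = c(2, 32),
                                                 min_split = c(2, 16),
                                                 min_leaf = c(1, 16)),
                             n_trials = 30, cv_folds = 5, seed = 42L) {
  X <- as.data.frame(X); y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  set.seed(seed)
  cand <- data.frame(
    n_trees = sample(search_space$n_trees[1]:search_space$n_trees[2],
                     n_trials, replace = TRUE),
    max_depth = sample(search_space$max_depth[1]:search_space$max_depth[2],
                       n_trials, replace = TRUE),
    min_split = sample(search_space$min_split[1]:search_space$min_split[2],
                       n_trials, replace = TRUE),
    min_leaf = sample(search_space$min_leaf[1]:search_space$min_leaf[2],
                      n_trials, replace = TRUE))
  fold <- make_folds(y, cv_folds)
  cv_eval <- function(hp) {
    accs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      m <- forest_fit(X[tr, , drop = FALSE], y[tr],
                      n_trees = hp$n_trees, max_depth = hp$max_depth,
                      min_split = hp$min_split, min_leaf = hp$min_leaf,
                      seed = seed + f)
      mean(predict(m, X[!tr, , drop = FALSE], type = "class") == y[!tr])
    }, numeric(1))
    accs
  }
  scores <- vapply(seq_len(n_trials), function(i)
    mean(cv_eval(cand[i, ]), na.rm = TRUE), numeric(1))
  best <- which.max(scores)
  hp <- cand[best, ]
  fold_metrics <- lapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    m <- forest_fit(X[tr, , drop = FALSE], y[tr],
                    n_trees = hp$n_trees, max_depth = hp$max_depth,
                    min_split = hp$min_split, min_leaf = hp$min_leaf,
                    seed = seed + f)
    classification_metrics(predict(m, X[!tr, , drop = FALSE],
                                   type = "class"), y[!tr])
  })
  model <- forest_fit(X, y, n_trees = hp$n_trees, max_depth = hp$max_depth,
                      min_split = hp$min_split, min_leaf = hp$min_leaf,
                      seed = seed)
  train_metrics <- classification_metrics(predict(model, X, type = "class"),
                                          y)
  list(model = model,
       report = list(hyperparameters = as.list(hp),
                     cv_accuracy = scores[best],
                     cv_fold_metrics = fold_metrics,
                     search_scores = scores,
                     training = train_metrics))
}

#' Partial dependence of the ensemble on one or two features
#'
#' For each point of an evenly spaced grid spanning the observed feature
#' range (50 points per feature by default), the feature is clamped to
#' the grid value in every training row and the mean predicted class-1
#' probability is recorded, marginalizing over the remaining features.
#'
#' @param model a `kmo_forest`.
#' @param X reference data (typically the training matrix).
#' @param features one or two feature names.
#' @param grid_points grid resolution per feature (default 50).
#' @return data.frame with the grid value(s) and `pd` (mean probability).
#' @export
partial_dependence <- function(model, X, features, grid_points = 50) {
  X <- as.data.frame(X)
  if (!all(features %in% model$feature_names))
    stop("unknown feature(s): ",
         paste(setdiff(features, model$feature_names), collapse = ", "))
  stopifnot(length(features) %in% 1:2)
  grids <- lapply(features, function(f)
    seq(min(X[[f]]), max(X[[f]]), length.out = grid_points))
  names(grids) <- features
  pts <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  pts$pd <- vapply(seq_len(nrow(pts)), function(i) {
    Xi <- X
    for (f in features) Xi[[f]] <- pts[i, f]
    mean(predict(model, Xi, type = "prob"))
  }, numeric(1))
  pts
}
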