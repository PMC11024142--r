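#' Fit a multiclass gradient-boosted tree model
#'
#' Softmax-objective boosted regression trees with second-order (Newton)
#' splits, per-tree row subsampling and per-tree feature subsampling.
#' Hyper-parameter defaults follow common gradient-boosting practice
#' (learning rate 0.3, depth 6, L2 penalty 1) and are recorded with the
#' model so runs can be reproduced.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y factor or character vector of class labels.
#' @param n_rounds boosting rounds (one tree per class per round).
#' @param learning_rate shrinkage applied to every leaf (default 0.3).
#' @param max_depth maximum tree depth (default 6).
#' @param min_child_weight minimum hessian sum per child (default 1).
#' @param lambda L2 regularisation on leaf weights (default 1).
#' @param gamma minimum split gain (default 0).
#' @param subsample fraction of rows drawn (without replacement) per tree.
#' @param colsample_count number of features drawn per tree (0 = all).
#' @param seed RNG seed.
#' @return a `gbt_model` object.
#' @export
gbt_fit <- function(x, y, n_rounds = 200, learning_rate = 0.3, max_depth = 6,
                    min_child_weight = 1, lambda = 1, gamma = 0,
                    subsample = 0.5, colsample_count = 0, seed = 1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  classes <- levels(y)
  if (length(classes) < 2) stop("need at least 2 classes")
  yi <- as.integer(y) - 1L
  fit <- with_seed(seed, gbt_fit_cpp(x, yi, length(classes),
                                     as.integer(n_rounds), learning_rate,
                                     as.integer(max_depth), min_child_weight,
                                     lambda, gamma, subsample,
                                     as.integer(colsample_count)))
  model <- list(booster = fit, classes = classes,
                n_features = ncol(x), feature_names = colnames(x),
                params = list(n_rounds = n_rounds,
                              learning_rate = learning_rate,
                              max_depth = max_depth,
                              min_child_weight = min_child_weight,
                              lambda = lambda, gamma = gamma,
                              subsample = subsample,
                              colsample_count = colsample_count,
                              seed = seed))
  class(model) <- "gbt_model"
  model
}

#' Predict class probabilities from a gbt_model
#'
#' @param object a `gbt_model`.
#' @param newdata samples x features matrix (same feature order as training).
#' @param ... unused.
#' @return samples x classes probability matrix (rows sum to 1).
#' @export
predict.gbt_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature count mismatch: model expects ", object$n_features)
  p <- gbt_predict_cpp(object$booster, newdata)
  colnames(p) <- object$classes
  rownames(p) <- rownames(newdata)
  p
}
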