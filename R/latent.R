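#' Default gradient-boosting hyperparameters
#'
#' The tuned settings used for both the feature booster and the final
#' classifier: learning rate 0.1, 463 boosting rounds, maximum depth 5,
#' minimum child weight 4, minimum split loss (gamma) 1.
#'
#' @param learning_rate shrinkage per boosting round.
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth.
#' @param min_child_weight minimum hessian sum per child.
#' @param gamma minimum loss reduction to split.
#' @return named list of class `"booster_params"`.
#' @export
booster_params <- function(learning_rate = 0.1, n_estimators = 463L,
                           max_depth = 5L, min_child_weight = 4L, gamma = 1) {
  stopifnot(learning_rate > 0, n_estimators >= 1L, max_depth >= 1L,
            min_child_weight >= 0, gamma >= 0)
  structure(list(learning_rate = learning_rate,
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight,
                 gamma = gamma),
            class = "booster_params")
}

# internal: shared xgb.train call (binary logistic, single thread for
# run-to-run determinism)
train_booster <- function(X, y, params, seed) {
  if (length(unique(y)) < 2L) stop("booster training requires both classes present")
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = params$learning_rate,
                  max_depth = params$max_depth,
                  min_child_weight = params$min_child_weight,
                  gamma = params$gamma,
                  nthread = 1L,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = params$n_estimators, verbose = 0)
}

#' Fit the feature booster and enumerate its leaves
#'
#' Trains a gradient-boosted tree ensemble on the original pair features and
#' records, per tree, the dense position of every leaf so samples can later
#' be encoded by one-of-K leaf membership.
#'
#' @param X numeric feature matrix (e.g. [feature_matrix()] output).
#' @param y binary 0/1 labels; both classes must be present.
#' @param params [booster_params()].
#' @param seed integer seed passed to the tree learner.
#' @return list of class `"feature_booster"` with the fitted `booster`, the
#'   `leaf_map` (per tree, a named map from native leaf node id to dense
#'   position), `n_trees`, `total_leaves`, and the training `feature_names`.
#' @export
fit_feature_booster <- function(X, y, params = booster_params(), seed = 42L) {
  X <- as.matrix(X)
  bst <- train_booster(X, y, params, seed)
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  leaves <- dump[dump$Feature == "Leaf", c("Tree", "Node")]
  tree_ids <- sort(unique(dump$Tree))
  leaf_map <- lapply(tree_ids, function(tr) {
    nodes <- sort(leaves$Node[leaves$Tree == tr])
    stats::setNames(seq_along(nodes), nodes)
  })
  names(leaf_map) <- tree_ids
  structure(list(booster = bst,
                 leaf_map = leaf_map,
                 n_trees = length(leaf_map),
                 total_leaves = sum(lengths(leaf_map)),
                 feature_names = colnames(X)),
            class = "feature_booster")
}

#' Encode samples by one-of-K leaf membership
#'
#' Routes each sample through every tree of the fitted feature booster and
#' marks the leaf it lands in: the encoding has one block of columns per
#' tree (tree-major, leaves in fixed fit-time order) and exactly one 1 per
#' block per sample, so every row sums to the number of trees.
#'
#' @param fb a `"feature_booster"` from [fit_feature_booster()].
#' @param X feature matrix with the columns the booster was fit on.
#' @return sparse binary [Matrix::sparseMatrix()] of size
#'   `nrow(X) x total_leaves`, column names `"tree<t>_leaf<l>"`.
#' @export
leaf_encode <- function(fb, X) {
  X <- as.matrix(X)
  if (!is.null(fb$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), fb$feature_names)) {
    stop("feature columns do not match the columns the booster was fit on")
  }
  leaf_idx <- predict(fb$booster, xgboost::xgb.DMatrix(X), predleaf = TRUE)
  leaf_idx <- matrix(leaf_idx, nrow = nrow(X))
  encode_leaf_matrix(leaf_idx, fb$leaf_map)
}

# internal: map an n x n_trees matrix of native leaf node ids to the sparse
# one-of-K encoding given the per-tree leaf maps
encode_leaf_matrix <- function(leaf_idx, leaf_map) {
  n <- nrow(leaf_idx)
  n_trees <- length(leaf_map)
  sizes <- lengths(leaf_map)
  offsets <- c(0L, cumsum(sizes))[seq_len(n_trees)]
  total <- sum(sizes)
  if (n_trees == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, 0L)))
  }
  stopifnot(ncol(leaf_idx) == n_trees)
  cols <- matrix(NA_integer_, n, n_trees)
  for (t in seq_len(n_trees)) {
    pos <- leaf_map[[t]][as.character(leaf_idx[, t])]
    if (anyNA(pos)) {
      stop(sprintf("internal error: unseen leaf id in tree %d", t))
    }
    cols[, t] <- offsets[t] + pos
  }
  out <- Matrix::sparseMatrix(i = rep(seq_len(n), n_trees),
                              j = as.integer(cols),
                              x = 1,
                              dims = c(n, total))
  colnames(out) <- unlist(lapply(seq_len(n_trees), function(t) {
    sprintf("tree%d_leaf%d", t, seq_len(sizes[t]))
  }))
  out
}

#' Stack original features with the leaf encoding
#'
#' Column-wise concatenation, original columns first; row order and count
#' are preserved. An empty encoding (zero trees) returns the original
#' features unchanged.
#'
#' @param original numeric feature matrix.
#' @param encoding leaf encoding from [leaf_encode()] (sparse or dense).
#' @return sparse feature matrix of width `ncol(original) + ncol(encoding)`.
#' @export
stack_features <- function(original, encoding) {
  if (nrow(original) != nrow(encoding)) {
    stop("original features and leaf encoding have different row counts")
  }
  cbind(methods::as(as.matrix(original), "CsparseMatrix"), encoding)
}
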