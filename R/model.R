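#' Sample balanced negatives from the unknown pairs
#'
#' Draws `n` distinct zero cells of the association matrix uniformly at
#' random without replacement; these unknown pairs serve as negative
#' examples alongside the known positives.
#'
#' @param assoc an [association_matrix()].
#' @param n number of negatives; defaults to the number of positives.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @return data.frame with `circRNA` and `disease` id columns.
#' @export
sample_negatives <- function(assoc, n = sum(assoc == 1), seed = 42L) {
  A <- unclass_matrix(assoc)
  zeros <- which(A == 0)
  if (n > length(zeros)) {
    stop(sprintf("requested %d negatives but only %d unknown pairs exist",
                 n, length(zeros)))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  pick <- zeros[sample.int(length(zeros), n)]
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  data.frame(circRNA = rownames(A)[(pick - 1L) %% nrow(A) + 1L],
             disease = colnames(A)[(pick - 1L) %/% nrow(A) + 1L],
             stringsAsFactors = FALSE)
}

#' Build the balanced labelled pair set
#'
#' All known positive pairs of the association matrix, plus an equal number
#' of sampled unknown pairs labelled 0.
#'
#' @inheritParams sample_negatives
#' @return data.frame with `circRNA`, `disease`, `label`.
#' @export
build_pair_dataset <- function(assoc, seed = 42L) {
  A <- unclass_matrix(assoc)
  pos <- which(A == 1, arr.ind = TRUE)
  positives <- data.frame(circRNA = rownames(A)[pos[, 1L]],
                          disease = colnames(A)[pos[, 2L]],
                          label = 1, stringsAsFactors = FALSE)
  negatives <- cbind(sample_negatives(assoc, nrow(positives), seed), label = 0)
  rbind(positives, negatives)
}

# internal: stratified fold assignment, deterministic given the RNG state
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("too few samples in a class for the requested fold count")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# internal: features for a pair list given an association matrix (GIP + NMF
# computed on that matrix), expression profiles and disease semantic sim
pair_features_from_inputs <- function(assoc, expr, dsim, pairs, labels, cfg) {
  sims <- integrated_similarities(assoc, expr, dsim,
                                  pearson_threshold = cfg$pearson_threshold,
                                  gamma_prime_circ = cfg$gamma_prime_circ,
                                  gamma_prime_disease = cfg$gamma_prime_disease)
  latent <- nmf_latent(assoc, rank = cfg$nmf_rank, seed = cfg$nmf_seed,
                       max_iter = cfg$nmf_max_iter, tol = cfg$nmf_tol)
  assemble_pair_features(sims$cs, sims$ds, latent, pairs, labels,
                         n_bins = cfg$n_bins, top_k = cfg$top_k)
}

#' Feature-engineering configuration
#'
#' @param pearson_threshold expression-similarity binarization cutoff.
#' @param gamma_prime_circ,gamma_prime_disease GIP bandwidth numerators.
#' @param n_bins histogram bins per node block.
#' @param top_k neighbourhood size for top-k statistics.
#' @param nmf_rank,nmf_seed,nmf_max_iter,nmf_tol NMF settings.
#' @return named list of class `"feature_config"`.
#' @export
feature_config <- function(pearson_threshold = 0.4,
                           gamma_prime_circ = 1, gamma_prime_disease = 1,
                           n_bins = 10L, top_k = 10L,
                           nmf_rank = 8L, nmf_seed = 42L,
                           nmf_max_iter = 500L, nmf_tol = 1e-6) {
  structure(list(pearson_threshold = pearson_threshold,
                 gamma_prime_circ = gamma_prime_circ,
                 gamma_prime_disease = gamma_prime_disease,
                 n_bins = as.integer(n_bins), top_k = as.integer(top_k),
                 nmf_rank = as.integer(nmf_rank),
                 nmf_seed = as.integer(nmf_seed),
                 nmf_max_iter = as.integer(nmf_max_iter), nmf_tol = nmf_tol),
            class = "feature_config")
}

# internal: fit feature booster + final classifier on one training set and
# score a test feature matrix
fit_stacked_and_score <- function(X_train, y_train, X_test, params, seed) {
  fb <- fit_feature_booster(X_train, y_train, params, seed)
  train_stacked <- stack_features(X_train, leaf_encode(fb, X_train))
  test_stacked <- stack_features(X_test, leaf_encode(fb, X_test))
  final <- train_booster(train_stacked, y_train, params, seed + 1L)
  list(feature_booster = fb, final = final,
       scores = predict(final, xgboost::xgb.DMatrix(test_stacked)))
}

#' Cross-validated evaluation of the full pipeline
#'
#' Builds a balanced pair set (all positives plus equally many sampled
#' unknowns), splits it into stratified folds, and per fold: optionally
#' zeroes the test-fold positives in the association matrix before
#' recomputing the GIP kernels and NMF factors (leakage control), extracts
#' pair features, fits the feature booster on the training fold, leaf-encodes
#' train and test, fits the final classifier on the stacked features, and
#' scores the test fold.
#'
#' @param assoc [association_matrix()].
#' @param expr [expression_profiles()] or `NULL`.
#' @param dsim disease semantic [similarity_matrix()] or `NULL`.
#' @param k number of folds (>= 2).
#' @param params [booster_params()].
#' @param cfg [feature_config()].
#' @param seed master integer seed controlling negative sampling, fold
#'   assignment, and booster seeds.
#' @param mask_test_in_similarity when `TRUE` (default) the test-fold
#'   positives are removed from the association matrix before computing
#'   GIP/NMF features for that fold; `FALSE` computes features once on the
#'   full matrix (the protocol implied by training on all known
#'   associations at once).
#' @param pair_set optional precomputed `circRNA`/`disease`/`label`
#'   data.frame overriding the internally built balanced set.
#' @return a [metrics_report()] with per-fold and mean ACC/AUC/PRE/REC/F1.
#' @export
cross_validate <- function(assoc, expr = NULL, dsim = NULL, k = 5L,
                           params = booster_params(), cfg = feature_config(),
                           seed = 42L, mask_test_in_similarity = TRUE,
                           pair_set = NULL) {
  stopifnot(k >= 2L)
  if (is.null(pair_set)) pair_set <- build_pair_dataset(assoc, seed)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed + 1L)
  fold <- stratified_folds(pair_set$label, k)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  pairs <- pair_set[, c("circRNA", "disease")]
  full_features <- NULL
  if (!mask_test_in_similarity) {
    full_features <- pair_features_from_inputs(assoc, expr, dsim, pairs,
                                               pair_set$label, cfg)
  }
  per_fold <- matrix(NA_real_, k, 5L,
                     dimnames = list(NULL, c("ACC", "AUC", "PRE", "REC", "F1")))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    y_train <- pair_set$label[train_idx]
    y_test <- pair_set$label[test_idx]
    if (length(unique(y_test)) < 2L || length(unique(y_train)) < 2L) {
      stop("a fold contains a single class; use fewer folds or more data")
    }
    if (mask_test_in_similarity) {
      A_fold <- unclass_matrix(assoc)
      held <- pair_set[test_idx, ][y_test == 1, ]
      A_fold[cbind(match(held$circRNA, rownames(A_fold)),
                   match(held$disease, colnames(A_fold)))] <- 0
      feats <- pair_features_from_inputs(association_matrix(A_fold), expr,
                                         dsim, pairs, pair_set$label, cfg)
    } else {
      feats <- full_features
    }
    X <- feature_matrix(feats)
    fit <- fit_stacked_and_score(X[train_idx, , drop = FALSE], y_train,
                                 X[test_idx, , drop = FALSE], params,
                                 seed + 100L + f)
    per_fold[f, ] <- compute_metrics(fit$scores, y_test)
  }
  metrics_report(per_fold)
}

#' Train on all labelled pairs and score candidate pairs
#'
#' Fits the feature booster and final classifier on the full balanced pair
#' set, then scores candidate (circRNA, disease) pairs; every score is a
#' probability in \[0, 1\]. By default all unknown pairs of the association
#' matrix are scored.
#'
#' @inheritParams cross_validate
#' @param candidate_pairs data.frame of `circRNA`, `disease` pairs to score;
#'   default: all zero cells of `assoc`.
#' @param score_threshold optional filter: keep only pairs scoring strictly
#'   above it (e.g. 0.9 for high-confidence reporting).
#' @param top_n optional: keep only the `top_n` highest-scoring pairs.
#' @return data.frame `circRNA`, `disease`, `score`, sorted by descending
#'   score.
#' @export
train_final_and_score <- function(assoc, expr = NULL, dsim = NULL,
                                  params = booster_params(),
                                  cfg = feature_config(), seed = 42L,
                                  candidate_pairs = NULL,
                                  score_threshold = NULL, top_n = NULL) {
  pair_set <- build_pair_dataset(assoc, seed)
  if (is.null(candidate_pairs)) {
    zeros <- which(unclass_matrix(assoc) == 0, arr.ind = TRUE)
    candidate_pairs <- data.frame(circRNA = rownames(assoc)[zeros[, 1L]],
                                  disease = colnames(assoc)[zeros[, 2L]],
                                  stringsAsFactors = FALSE)
  }
  all_pairs <- rbind(pair_set[, c("circRNA", "disease")],
                     candidate_pairs[, c("circRNA", "disease")])
  feats <- pair_features_from_inputs(assoc, expr, dsim, all_pairs, NULL, cfg)
  X <- feature_matrix(feats)
  n_lab <- nrow(pair_set)
  fit <- fit_stacked_and_score(X[seq_len(n_lab), , drop = FALSE],
                               pair_set$label,
                               X[-seq_len(n_lab), , drop = FALSE],
                               params, seed + 100L)
  out <- data.frame(candidate_pairs[, c("circRNA", "disease")],
                    score = fit$scores, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$circRNA, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(score_threshold)) out <- out[out$score > score_threshold, , drop = FALSE]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}
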