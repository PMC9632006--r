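#' Classification metrics for scored pairs
#'
#' Standard binary-classification metrics. AUC is the rank-based
#' (Wilcoxon-Mann-Whitney) probability that a random positive outscores a
#' random negative, ties counted one half. ACC, PRE, REC and F1 use the
#' confusion matrix at `threshold` (scores strictly greater than the
#' threshold are called positive); F1 is the harmonic mean of precision and
#' recall. Precision (and hence F1) is defined as 0 when nothing is called
#' positive.
#'
#' @param scores numeric score vector in \[0, 1\].
#' @param labels binary 0/1 vector; both classes must be present.
#' @param threshold classification cutoff; default 0.5.
#' @return named numeric vector `c(ACC, AUC, PRE, REC, F1)`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- mean(pred == labels)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- tp / (tp + fn)
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  c(ACC = acc, AUC = auc, PRE = pre, REC = rec, F1 = f1)
}

#' Summarize per-fold metrics
#'
#' @param fold_metrics matrix or data.frame, one row per fold, columns
#'   ACC/AUC/PRE/REC/F1.
#' @return list of class `"metrics_report"` with `folds` (data.frame) and
#'   `mean` (named vector of arithmetic fold means).
#' @export
metrics_report <- function(fold_metrics) {
  folds <- as.data.frame(fold_metrics)
  structure(list(folds = cbind(fold = seq_len(nrow(folds)), folds),
                 mean = colMeans(folds)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", nrow(x$folds)))
  print(round(x$folds, 4), row.names = FALSE)
  cat("mean:\n")
  print(round(x$mean, 4))
  invisible(x)
}
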