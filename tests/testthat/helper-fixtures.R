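# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately use naive algorithms (double loops, Floyd-Warshall,
# exhaustive pair counting) so they share no code path with the package.

random_binary_matrix <- function(n, m, p = 0.3) {
  matrix(rbinom(n * m, 1, p), n, m,
         dimnames = list(paste0("c", seq_len(n)), paste0("d", seq_len(m))))
}

random_similarity <- function(n) {
  s <- matrix(runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  s
}

# GIP kernel by literal double loop over profiles
oracle_gip <- function(A, axis, gamma_prime = 1) {
  Y <- if (axis == "circRNA") A else t(A)
  n <- nrow(Y)
  gamma <- gamma_prime / (mean(sapply(seq_len(n), function(i) sum(Y[i, ]^2))))
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-gamma * sum((Y[i, ] - Y[j, ])^2))
    }
  }
  dimnames(K) <- list(rownames(Y), rownames(Y))
  K
}

# all-pairs shortest-path distances by Floyd-Warshall on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# shortest-path counts sigma[s, t] by dynamic programming over distance layers
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# normalized degree, component-scaled closeness, normalized betweenness
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  deg <- rowSums(adj)
  res <- matrix(0, n, 4,
                dimnames = list(rownames(adj),
                                c("n_neighbors", "degree_c", "closeness_c",
                                  "betweenness_c")))
  for (v in seq_len(n)) {
    reach <- d[v, -v][is.finite(d[v, -v])]
    m1 <- length(reach)
    clo <- if (m1 > 0) (m1 / sum(reach)) * (m1 / (n - 1)) else 0
    btw <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (is.finite(d[s, t]) && sigma[s, t] > 0 &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw <- btw + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    res[v, ] <- c(deg[v], if (n > 1) deg[v] / (n - 1) else 0, clo,
                  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else 0)
  }
  res
}

# AUC by exhaustive positive-negative pair counting, ties one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

oracle_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- tp / (tp + fn)
  c(ACC = (tp + tn) / length(labels),
    AUC = oracle_auc(scores, labels),
    PRE = pre, REC = rec,
    F1 = if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0)
}

# tiny synthetic dataset + cheap booster settings for fast model tests
tiny_dataset <- function(seed = 1L, n_circ = 40L, n_dis = 20L) {
  generate_dataset(synthetic_config(n_circ = n_circ, n_dis = n_dis,
                                    n_samples = 12L, seed = seed))
}

cheap_params <- function(n_estimators = 30L) {
  booster_params(n_estimators = n_estimators, max_depth = 3L)
}

# light regularization variant for very small fixtures, where the tuned
# min_child_weight/gamma defaults would suppress every split
easy_params <- function(n_estimators = 30L) {
  booster_params(n_estimators = n_estimators, max_depth = 3L,
                 min_child_weight = 1L, gamma = 0)
}
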