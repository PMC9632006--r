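#' Mean and histogram of a node's similarity scores
#'
#' Summarizes a node's off-diagonal row of a similarity matrix by its mean
#' and an equal-width histogram of bin counts over \[0, 1\]. Bins are
#' left-closed, `[ (b-1)/n_bins, b/n_bins )`, with 1 assigned to the last
#' bin. A one-node network (no neighbours) yields mean 0 and an all-zero
#' histogram.
#'
#' @param sim [similarity_matrix()].
#' @param node identifier present in `sim`.
#' @param n_bins number of histogram bins; default 10.
#' @return list with `mean` and integer `histogram` of length `n_bins`.
#' @export
similarity_stats <- function(sim, node, n_bins = 10L) {
  i <- match(node, rownames(sim))
  if (is.na(i)) stop(sprintf("unknown node id '%s'", node))
  scores <- unclass_matrix(sim)[i, -i]
  list(mean = if (length(scores)) mean(scores) else 0,
       histogram = bin_counts(scores, n_bins))
}

# internal: equal-width bin counts over [0, 1], last bin right-closed
bin_counts <- function(x, n_bins) {
  if (length(x) == 0L) return(integer(n_bins))
  tabulate(pmin(floor(x * n_bins) + 1L, n_bins), nbins = n_bins)
}

#' Threshold a similarity matrix into an unweighted graph
#'
#' Nodes are the matrix ids; an undirected edge joins i and j (i != j) when
#' their similarity strictly exceeds the global mean of the off-diagonal
#' entries. With all off-diagonal entries equal the graph has no edges.
#'
#' @param sim [similarity_matrix()] with at least 2 nodes.
#' @return an [igraph::graph] over the similarity ids.
#' @export
build_similarity_graph <- function(sim) {
  s <- unclass_matrix(sim)
  n <- nrow(s)
  stopifnot(n >= 2L)
  off <- s[row(s) != col(s)]
  adj <- (s > mean(off)) * 1
  diag(adj) <- 0
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Graph-theory features of one node
#'
#' Degree centrality is degree / (n - 1). Closeness uses the
#' component-scaled convention: within the node's connected component of
#' size m, closeness is `(m - 1) / sum(d(v, u))`, scaled by
#' `(m - 1) / (n - 1)` so values stay comparable across components;
#' isolated nodes score 0. Betweenness is shortest-path betweenness
#' normalized by `(n - 1)(n - 2) / 2`.
#'
#' @param graph igraph graph from [build_similarity_graph()].
#' @param node node identifier.
#' @return list with `n_neighbors`, `degree_c`, `closeness_c`,
#'   `betweenness_c`, all in \[0, 1\] except the raw neighbour count.
#' @export
centrality_features <- function(graph, node) {
  feats <- all_centralities(graph)
  i <- match(node, rownames(feats))
  if (is.na(i)) stop(sprintf("node '%s' not in graph", node))
  as.list(feats[i, ])
}

# internal: centralities for every node at once (one igraph pass)
all_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  degree_c <- if (n > 1L) deg / (n - 1L) else rep(0, n)
  d <- igraph::distances(graph)
  closeness_c <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    m1 <- length(reach)                      # component size - 1
    if (m1 == 0L) return(0)
    (m1 / sum(reach)) * (m1 / (n - 1L))
  }, numeric(1L))
  btw <- igraph::betweenness(graph, directed = FALSE)
  betweenness_c <- if (n > 2L) btw / ((n - 1L) * (n - 2L) / 2) else rep(0, n)
  out <- cbind(n_neighbors = deg, degree_c = degree_c,
               closeness_c = closeness_c, betweenness_c = betweenness_c)
  rownames(out) <- igraph::V(graph)$name
  out
}

#' Mean and histogram over a node's top-k most similar neighbours
#'
#' Ranks all other nodes by similarity to `node` (descending; ties broken
#' by id order), keeps the top `k` (all, if fewer than `k` others exist),
#' and returns the mean and an equal-width histogram of their similarity
#' scores.
#'
#' @inheritParams similarity_stats
#' @param k neighbourhood size; default 10.
#' @return list with `mean` and `histogram`.
#' @export
topk_neighbor_stats <- function(sim, node, k = 10L, n_bins = 10L) {
  i <- match(node, rownames(sim))
  if (is.na(i)) stop(sprintf("unknown node id '%s'", node))
  scores <- unclass_matrix(sim)[i, -i]
  if (length(scores) == 0L) {
    return(list(mean = 0, histogram = integer(n_bins)))
  }
  top <- scores[order(-scores)][seq_len(min(k, length(scores)))]
  list(mean = mean(top), histogram = bin_counts(top, n_bins))
}

# internal: full per-node feature block for every id of one similarity matrix
node_feature_block <- function(sim, n_bins = 10L, top_k = 10L) {
  n <- nrow(sim)
  ids <- rownames(sim)
  cent <- all_centralities(build_similarity_graph(sim))
  s <- unclass_matrix(sim)
  rows <- lapply(seq_len(n), function(i) {
    scores <- s[i, -i]
    top <- if (length(scores)) {
      scores[order(-scores)][seq_len(min(top_k, length(scores)))]
    } else numeric(0)
    c(mean_sim = if (length(scores)) mean(scores) else 0,
      stats::setNames(bin_counts(scores, n_bins), paste0("hist_", seq_len(n_bins))),
      cent[i, ],
      topk_mean = if (length(top)) mean(top) else 0,
      stats::setNames(bin_counts(top, n_bins), paste0("topk_hist_", seq_len(n_bins))))
  })
  block <- do.call(rbind, rows)
  rownames(block) <- ids
  block
}

#' Assemble the per-pair original feature table
#'
#' One row per (circRNA, disease) candidate pair. Columns, in fixed order:
#' the circRNA node block (mean similarity, `n_bins` histogram counts,
#' neighbour count, degree/closeness/betweenness centrality, top-k mean,
#' `n_bins` top-k histogram counts), the analogous disease node block, the
#' circRNA NMF factor row, and the disease NMF factor column. Width is
#' `2 * (2 * n_bins + 6) + 2 * rank`.
#'
#' @param cs integrated circRNA [similarity_matrix()].
#' @param ds integrated disease [similarity_matrix()].
#' @param latent an [nmf_latent()] fit of the association matrix.
#' @param pairs data.frame (or 2-column matrix) of circRNA and disease ids.
#' @param labels optional 0/1/NA label vector, one per pair.
#' @param n_bins histogram bins per block.
#' @param top_k neighbourhood size.
#' @return data.frame with `circRNA`, `disease`, `label`, and numeric
#'   feature columns; classed `"pair_features"`.
#' @export
assemble_pair_features <- function(cs, ds, latent, pairs, labels = NULL,
                                   n_bins = 10L, top_k = 10L) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2L)
  circ <- as.character(pairs[[1L]])
  dis <- as.character(pairs[[2L]])
  ci <- match(circ, rownames(cs))
  di <- match(dis, rownames(ds))
  if (anyNA(ci)) stop(sprintf("unresolvable circRNA id '%s'", circ[which(is.na(ci))[1L]]))
  if (anyNA(di)) stop(sprintf("unresolvable disease id '%s'", dis[which(is.na(di))[1L]]))
  c_block <- node_feature_block(cs, n_bins, top_k)
  d_block <- node_feature_block(ds, n_bins, top_k)
  W <- latent$circ_factors
  H <- latent$disease_factors
  if (!all(circ %in% rownames(W)) || !all(dis %in% colnames(H))) {
    stop("NMF latent factors do not cover all requested pair ids")
  }
  feat <- cbind(c_block[ci, , drop = FALSE],
                d_block[di, , drop = FALSE],
                W[circ, , drop = FALSE],
                t(H)[dis, , drop = FALSE])
  colnames(feat) <- c(paste0("circ_", colnames(c_block)),
                      paste0("dis_", colnames(d_block)),
                      paste0("circ_nmf_", seq_len(latent$rank)),
                      paste0("dis_nmf_", seq_len(latent$rank)))
  if (is.null(labels)) labels <- rep(NA_real_, length(circ))
  stopifnot(length(labels) == length(circ))
  out <- data.frame(circRNA = circ, disease = dis, label = as.numeric(labels),
                    feat, check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("pair_features", class(out))
  out
}

#' Numeric feature matrix of a pair feature table
#'
#' @param x a `"pair_features"` data.frame.
#' @return numeric matrix of the feature columns only.
#' @export
feature_matrix <- function(x) {
  cols <- setdiff(colnames(x), c("circRNA", "disease", "label"))
  as.matrix(as.data.frame(x)[, cols, drop = FALSE])
}
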