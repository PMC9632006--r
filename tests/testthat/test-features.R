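test_that("similarity stats give the off-diagonal mean and bin counts", {
  ids <- paste0("v", 1:5)
  s <- matrix(1, 5, 5, dimnames = list(ids, ids))
  st <- similarity_stats(similarity_matrix(s), "v1", n_bins = 10)
  expect_equal(st$mean, 1)
  expect_equal(st$histogram, c(rep(0L, 9), 4L))

  s2 <- matrix(c(1, 0.05, 0.15,
                 0.05, 1, 0.5,
                 0.15, 0.5, 1), 3, 3,
               dimnames = list(ids[1:3], ids[1:3]))
  st2 <- similarity_stats(similarity_matrix(s2), "v1")
  expect_equal(st2$mean, 0.10)
  expect_equal(st2$histogram, c(1L, 1L, rep(0L, 8)))

  lone <- similarity_matrix(matrix(1, 1, 1, dimnames = list("v1", "v1")))
  st3 <- similarity_stats(lone, "v1")
  expect_equal(st3$mean, 0)
  expect_equal(st3$histogram, integer(10))

  expect_error(similarity_stats(similarity_matrix(s), "nope"), "unknown node")
})

test_that("the similarity graph thresholds strictly at the global off-diagonal mean", {
  ids <- paste0("v", 1:3)
  flat <- matrix(0.5, 3, 3); diag(flat) <- 1; dimnames(flat) <- list(ids, ids)
  g <- build_similarity_graph(similarity_matrix(flat))
  expect_equal(igraph::ecount(g), 0)   # all equal: strict inequality, no edges

  s <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, 3, dimnames = list(ids, ids))
  g2 <- build_similarity_graph(similarity_matrix(s))
  expect_equal(igraph::ecount(g2), 1)  # only 0.9 > mean 0.3667
  expect_true(igraph::are_adjacent(g2, "v1", "v2"))
})

test_that("graph construction is equivariant under id permutation", {
  set.seed(21)
  s <- random_similarity(8)
  g <- build_similarity_graph(similarity_matrix(s))
  perm <- sample(8)
  gp <- build_similarity_graph(similarity_matrix(s[perm, perm]))
  edges <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_equal(edges(gp), edges(g))
})

test_that("centralities match hand-derived values on canonical graphs", {
  # path a-b-c: center has degree, closeness and betweenness all 1
  adj <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  b <- centrality_features(g, "b")
  expect_equal(b$degree_c, 1)
  expect_equal(b$closeness_c, 1)
  expect_equal(b$betweenness_c, 1)
  a <- centrality_features(g, "a")
  expect_equal(a$closeness_c, 2 / 3)
  expect_equal(a$betweenness_c, 0)

  # complete graph: degree 1, betweenness 0
  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("v", 1:5)
  f <- centrality_features(full, "v3")
  expect_equal(f$degree_c, 1)
  expect_equal(f$betweenness_c, 0)

  # isolated node scores zero everywhere
  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- paste0("v", 1:3)
  z <- centrality_features(iso, "v1")
  expect_equal(unlist(z), c(n_neighbors = 0, degree_c = 0,
                            closeness_c = 0, betweenness_c = 0))
})

test_that("centralities match the brute-force shortest-path oracle on random graphs", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    adj <- matrix(rbinom(n * n, 1, 0.35), n, n)
    adj <- pmax(adj, t(adj)); diag(adj) <- 0
    ids <- paste0("v", seq_len(n))
    dimnames(adj) <- list(ids, ids)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expected <- oracle_centralities(adj)
    for (v in ids) {
      got <- unlist(centrality_features(g, v))
      expect_equal(got, expected[v, ], tolerance = 1e-9)
    }
  }
})

test_that("top-k neighbour stats rank by similarity with stable ties", {
  ids <- paste0("v", 1:4)
  s <- matrix(c(1, 0.9, 0.8, 0.1,
                0.9, 1, 0.2, 0.2,
                0.8, 0.2, 1, 0.2,
                0.1, 0.2, 0.2, 1), 4, 4, dimnames = list(ids, ids))
  sm <- similarity_matrix(s)
  expect_equal(topk_neighbor_stats(sm, "v1", k = 2)$mean, 0.85)
  # k exceeding n - 1 reduces to the plain off-diagonal mean
  expect_equal(topk_neighbor_stats(sm, "v1", k = 10)$mean,
               similarity_stats(sm, "v1")$mean)
  # all-equal similarities: mean is that value for any k
  flat <- matrix(0.4, 4, 4); diag(flat) <- 1; dimnames(flat) <- list(ids, ids)
  expect_equal(topk_neighbor_stats(similarity_matrix(flat), "v2", k = 2)$mean, 0.4)
})

test_that("pair feature tables have the documented width and are deterministic", {
  ds <- tiny_dataset(seed = 3)
  sims <- integrated_similarities(ds$assoc, ds$expr, ds$dsim)
  lat <- nmf_latent(ds$assoc, rank = 4, seed = 1)
  pairs <- data.frame(circRNA = c("circ_001", "circ_002", "circ_001"),
                      disease = c("disease_01", "disease_02", "disease_01"))
  ft <- assemble_pair_features(sims$cs, sims$ds, lat, pairs, labels = c(1, 0, 1))
  # width = 2 blocks of (mean + 10 hist + 4 centrality-ish + topk mean + 10) + 2 * rank
  expect_equal(ncol(feature_matrix(ft)), 2 * (2 * 10 + 6) + 2 * 4)
  expect_false(anyNA(feature_matrix(ft)))
  # identical pairs produce identical rows
  expect_equal(feature_matrix(ft)[1, ], feature_matrix(ft)[3, ])
  # swapping pair order swaps rows only
  ft2 <- assemble_pair_features(sims$cs, sims$ds, lat, pairs[c(2, 1, 3), ],
                                labels = c(0, 1, 1))
  expect_equal(feature_matrix(ft2)[1, ], feature_matrix(ft)[2, ])
  expect_error(assemble_pair_features(sims$cs, sims$ds, lat,
                                      data.frame(circRNA = "ghost",
                                                 disease = "disease_01")),
               "unresolvable circRNA")
})
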