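make_expr <- function(rows) {
  expression_profiles(do.call(rbind, rows),
                      circ_ids = paste0("c", seq_along(rows)),
                      sample_ids = paste0("s", seq_len(length(rows[[1]]))))
}

test_that("expression similarity binarizes Pearson correlation at the threshold", {
  X <- make_expr(list(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))
  cs <- expression_profile_similarity(X, threshold = 0.4)
  expect_equal(cs["c1", "c2"], 1)   # r = 1
  expect_equal(cs["c1", "c3"], 0)   # r = -1
  expect_equal(diag(unclass(cs)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(cs), t(unclass(cs)))
})

test_that("constant profiles get similarity 0 so integration falls back to GIP", {
  X <- make_expr(list(c(1, 1, 1), c(1, 2, 3)))
  cs <- expression_profile_similarity(X)
  expect_equal(cs["c1", "c2"], 0)
  expect_equal(cs["c1", "c1"], 1)   # self-similarity still forced
})

test_that("expression similarity is invariant to affine rescaling of profiles", {
  set.seed(5)
  base <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("c", 1:5), paste0("s", 1:8)))
  scaled <- base * 3.7 + 11
  cs1 <- expression_profile_similarity(expression_profiles(base))
  cs2 <- expression_profile_similarity(expression_profiles(scaled))
  expect_equal(unclass(cs1), unclass(cs2))
})

test_that("expanding to a wider circRNA universe zeroes rows without expression", {
  X <- make_expr(list(c(1, 2, 3), c(1, 2, 4)))
  cs <- expression_profile_similarity(X, ids = c("c1", "c2", "cZ"))
  expect_equal(dim(cs), c(3L, 3L))
  expect_true(all(cs["cZ", ] == 0))
  expect_equal(cs["c1", "c2"], 1)
})

test_that("GIP kernel reproduces the hand-derived two-profile value", {
  A <- association_matrix(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
                                 dimnames = list(c("c1", "c2"), c("d1", "d2"))))
  K <- gip_kernel(A, "circRNA", gamma_prime = 1)
  # gamma = 1 / ((1/2)(1 + 1)) = 1; ||y1 - y2||^2 = 2
  expect_equal(K["c1", "c2"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(unclass(K)), rep(1, 2), ignore_attr = TRUE)
})

test_that("GIP kernel matches a brute-force double loop on random matrices", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    m <- sample(2:10, 1)
    A <- random_binary_matrix(n, m, p = 0.4)
    if (sum(A) == 0) A[1, 1] <- 1
    am <- association_matrix(A)
    for (axis in c("circRNA", "disease")) {
      expect_equal(max(abs(unclass(gip_kernel(am, axis)) - oracle_gip(A, axis))),
                   0, tolerance = 1e-12)
    }
  }
})

test_that("GIP kernel is equivariant under simultaneous row and column permutation", {
  set.seed(9)
  A <- random_binary_matrix(8, 6, 0.4); A[1, 1] <- 1
  K <- unclass(gip_kernel(association_matrix(A), "circRNA"))
  perm <- sample(nrow(A))
  Kp <- unclass(gip_kernel(association_matrix(A[perm, ]), "circRNA"))
  expect_equal(Kp, K[perm, perm])
})

test_that("GIP kernel on an all-zero matrix reports an undefined bandwidth", {
  A <- association_matrix(matrix(0, 2, 2, dimnames = list(c("c1", "c2"),
                                                          c("d1", "d2"))))
  expect_error(gip_kernel(A, "circRNA"), "division by zero")
})

test_that("similarity integration prefers the primary value and falls back elsewhere", {
  set.seed(13)
  n <- 7
  ids <- paste0("v", 1:n)
  p <- matrix(rbinom(n * n, 1, 0.4), n, n); p <- p * t(p); diag(p) <- 1
  dimnames(p) <- list(ids, ids)
  f <- random_similarity(n)
  f[f == 0] <- 0.01  # strictly positive fallback
  out <- unclass(integrate_similarity(similarity_matrix(p), similarity_matrix(f)))
  expect_equal(out[p != 0], p[p != 0])
  expect_equal(out[p == 0], f[p == 0])
  # support never shrinks: union of supports
  expect_equal(out != 0, (p != 0) | (f != 0))
})

test_that("integration handles the degenerate all-zero and identical cases", {
  ids <- c("a", "b")
  z <- matrix(0, 2, 2, dimnames = list(ids, ids))
  f <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(ids, ids))
  expect_equal(unclass(integrate_similarity(similarity_matrix(z), similarity_matrix(f))),
               f)
  expect_equal(unclass(integrate_similarity(similarity_matrix(f), similarity_matrix(f))),
               f)
  g <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("a", "x"), c("a", "x")))
  expect_error(integrate_similarity(similarity_matrix(f), similarity_matrix(g)),
               "share ids")
})
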