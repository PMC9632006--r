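#' Non-negative matrix factorization of the association matrix
#'
#' Factors the binary association matrix A (n_c x n_d) as W %*% H with
#' W >= 0 (n_c x rank) and H >= 0 (rank x n_d) by Lee-Seung multiplicative
#' updates minimizing the Frobenius reconstruction loss. The row of W for a
#' circRNA and the column of H for a disease serve as latent link-prediction
#' features. Updates are monotone (the loss never increases), and the fit is
#' deterministic given `seed`.
#'
#' @param assoc an [association_matrix()] (any non-negative matrix works).
#' @param rank factorization rank; must satisfy `rank <= min(dim(assoc))`.
#' @param seed integer seed for the uniform random initialization.
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol relative-change stopping tolerance on the loss.
#' @return list of class `"nmf_latent"` with `circ_factors` (W, rownames =
#'   circRNA ids), `disease_factors` (H, colnames = disease ids), `rank`,
#'   `loss` (per-iteration Frobenius loss), `iterations`.
#' @export
nmf_latent <- function(assoc, rank = 8L, seed = 42L, max_iter = 500L,
                       tol = 1e-6) {
  A <- unclass_matrix(assoc)
  stopifnot(all(A >= 0), rank >= 1L)
  if (rank > min(dim(A))) {
    stop(sprintf("NMF rank %d exceeds min(dim) = %d", rank, min(dim(A))))
  }
  n <- nrow(A); m <- ncol(A)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  W <- matrix(stats::runif(n * rank), n, rank)
  H <- matrix(stats::runif(rank * m), rank, m)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  eps <- .Machine$double.eps
  loss <- numeric(max_iter)
  prev <- norm(A - W %*% H, "F")^2
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    loss[it] <- norm(A - W %*% H, "F")^2
    if (prev - loss[it] <= tol * max(prev, eps)) break
    prev <- loss[it]
  }
  rownames(W) <- rownames(A)
  colnames(H) <- colnames(A)
  structure(list(circ_factors = W, disease_factors = H, rank = as.integer(rank),
                 loss = loss[seq_len(it)], iterations = it),
            class = "nmf_latent")
}
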