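#' Binarized expression-profile similarity
#'
#' Pearson correlation between every pair of circRNA expression profiles,
#' thresholded to a binary similarity: entry (i, j) is 1 when r(X_i, X_j)
#' exceeds `threshold` (strictly), else 0. The diagonal is forced to 1 for
#' every circRNA that has an expression record. Profiles with zero variance
#' have undefined Pearson correlation; their r is defined as 0, so their
#' similarity is 0 and the integrated similarity falls back to the GIP
#' kernel.
#'
#' @param expr an [expression_profiles()] matrix.
#' @param threshold binarization cutoff in \[-1, 1\]; default 0.4.
#' @param ids optional full circRNA universe. Ids without an expression
#'   record get an all-zero row and column (diagonal included), so the
#'   integrated similarity uses the GIP kernel for them everywhere.
#' @return binary [similarity_matrix()] over `ids` (or over `rownames(expr)`).
#' @export
expression_profile_similarity <- function(expr, threshold = 0.4, ids = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= -1, threshold <= 1)
  x <- unclass_matrix(expr)
  sds <- apply(x, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- 0          # zero-variance profiles: define r = 0
  r[sds == 0, ] <- 0
  r[, sds == 0] <- 0
  cs <- (r > threshold) * 1
  diag(cs) <- 1
  dimnames(cs) <- list(rownames(expr), rownames(expr))
  if (!is.null(ids)) {
    ids <- trimws(as.character(ids))
    full <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    present <- intersect(ids, rownames(cs))
    full[present, present] <- cs[present, present]
    cs <- full
  }
  similarity_matrix(cs)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Interaction profiles are the rows (circRNA axis) or columns (disease
#' axis) of the binary association matrix A. The kernel is
#' `K(i, j) = exp(-gamma * ||y_i - y_j||^2)` with the bandwidth normalized
#' by the mean squared profile norm:
#' `gamma = gamma_prime / ((1/n) * sum_i ||y_i||^2)`.
#'
#' @param assoc an [association_matrix()].
#' @param axis `"circRNA"` (rows of A) or `"disease"` (columns of A).
#' @param gamma_prime positive bandwidth numerator; default 1.
#' @return [similarity_matrix()] with unit diagonal and entries in (0, 1\].
#' @export
gip_kernel <- function(assoc, axis = c("circRNA", "disease"), gamma_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(gamma_prime), length(gamma_prime) == 1L, gamma_prime > 0)
  A <- unclass_matrix(assoc)
  Y <- if (axis == "circRNA") A else t(A)
  sq_norms <- rowSums(Y^2)
  if (sum(sq_norms) == 0) stop("GIP bandwidth undefined (division by zero)")
  gamma <- gamma_prime / mean(sq_norms)
  # ||y_i - y_j||^2 = ||y_i||^2 + ||y_j||^2 - 2 <y_i, y_j>
  d2 <- outer(sq_norms, sq_norms, `+`) - 2 * tcrossprod(Y)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  dimnames(K) <- list(rownames(Y), rownames(Y))
  similarity_matrix(K)
}

#' Integrate a primary similarity with a GIP fallback
#'
#' Piecewise fusion: the output takes the primary similarity wherever it is
#' nonzero and the fallback elsewhere. Used both for circRNAs
#' (expression-profile similarity backed by the circRNA GIP kernel) and for
#' diseases (semantic similarity backed by the disease GIP kernel).
#'
#' @param primary,fallback [similarity_matrix()] objects over the same ids
#'   in the same order.
#' @return integrated [similarity_matrix()].
#' @export
integrate_similarity <- function(primary, fallback) {
  if (!identical(dim(primary), dim(fallback)) ||
      !identical(rownames(primary), rownames(fallback))) {
    stop("primary and fallback similarity matrices must share ids and ordering")
  }
  p <- unclass_matrix(primary)
  f <- unclass_matrix(fallback)
  out <- ifelse(p != 0, p, f)
  dimnames(out) <- dimnames(p)
  similarity_matrix(out)
}

#' Build both integrated similarity matrices
#'
#' Convenience wrapper: computes the expression-profile similarity expanded
#' to the association matrix's circRNA universe, the two GIP kernels, and
#' the piecewise integrations for circRNAs and diseases.
#'
#' @param assoc [association_matrix()].
#' @param expr [expression_profiles()] or `NULL` (circRNA similarity is then
#'   pure GIP).
#' @param dsim disease semantic [similarity_matrix()] or `NULL` (disease
#'   similarity is then pure GIP); must cover the association diseases.
#' @param pearson_threshold binarization cutoff for expression similarity.
#' @param gamma_prime_circ,gamma_prime_disease GIP bandwidth numerators.
#' @return list with `cs` (circRNA) and `ds` (disease) integrated
#'   similarity matrices.
#' @export
integrated_similarities <- function(assoc, expr = NULL, dsim = NULL,
                                    pearson_threshold = 0.4,
                                    gamma_prime_circ = 1,
                                    gamma_prime_disease = 1) {
  cs_gs <- gip_kernel(assoc, "circRNA", gamma_prime_circ)
  ds_gs <- gip_kernel(assoc, "disease", gamma_prime_disease)
  cs <- if (is.null(expr)) cs_gs else {
    cs_ep <- expression_profile_similarity(expr, pearson_threshold,
                                           ids = rownames(assoc))
    integrate_similarity(cs_ep, cs_gs)
  }
  ds <- if (is.null(dsim)) ds_gs else {
    d_ids <- colnames(assoc)
    if (!all(d_ids %in% rownames(dsim))) {
      stop("disease similarity matrix does not cover all association diseases; run harmonize_ids() first")
    }
    ds_ss <- similarity_matrix(unclass_matrix(dsim)[d_ids, d_ids, drop = FALSE])
    integrate_similarity(ds_ss, ds_gs)
  }
  list(cs = cs, ds = ds)
}
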