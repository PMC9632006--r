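#' Core matrix containers
#'
#' The pipeline works on three labelled base-R matrices:
#' an association matrix (binary, circRNA x disease), an expression profile
#' set (numeric, circRNA x sample), and square symmetric similarity matrices
#' with values in \[0, 1\]. Constructors validate invariants once so downstream
#' code can assume them.
#'
#' @name containers
NULL

#' Construct a binary circRNA x disease association matrix
#'
#' @param values numeric matrix with entries in `{0, 1}`.
#' @param circ_ids,disease_ids character vectors of unique identifiers; taken
#'   from `dimnames(values)` when omitted.
#' @return a base matrix of 0/1 with `circ_ids` as rownames and `disease_ids`
#'   as colnames, classed `"assoc_matrix"`.
#' @export
association_matrix <- function(values, circ_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(circ_ids) || is.null(disease_ids)) {
    stop("association matrix requires circRNA and disease identifiers")
  }
  circ_ids <- trimws(as.character(circ_ids))
  disease_ids <- trimws(as.character(disease_ids))
  if (anyDuplicated(circ_ids)) stop("duplicate circRNA identifiers")
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("association matrix must have at least one circRNA and one disease")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || !all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)))[1L]
    stop(sprintf("association matrix entries must be 0/1 (offending cell [%d, %d])",
                 (bad - 1L) %% nrow(values) + 1L, (bad - 1L) %/% nrow(values) + 1L))
  }
  dimnames(values) <- list(circ_ids, disease_ids)
  class(values) <- c("assoc_matrix", class(values))
  values
}

#' Construct an expression profile set
#'
#' @param values numeric matrix, circRNAs in rows, samples in columns.
#' @param circ_ids,sample_ids identifiers; taken from dimnames when omitted.
#' @return numeric matrix classed `"expression_profiles"`.
#' @export
expression_profiles <- function(values, circ_ids = rownames(values),
                                sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(circ_ids)) stop("expression profiles require circRNA identifiers")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  circ_ids <- trimws(as.character(circ_ids))
  if (anyDuplicated(circ_ids)) stop("duplicate circRNA identifiers")
  if (ncol(values) < 2L) {
    stop("expression profiles need at least 2 samples (Pearson correlation needs >= 2 points)")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite expression value at row '%s', column '%s'",
                 circ_ids[(bad - 1L) %% nrow(values) + 1L],
                 sample_ids[(bad - 1L) %/% nrow(values) + 1L]))
  }
  dimnames(values) <- list(circ_ids, as.character(sample_ids))
  class(values) <- c("expression_profiles", class(values))
  values
}

#' Construct a similarity matrix
#'
#' @param values square numeric matrix, symmetric within `tol`, entries in
#'   \[0, 1\].
#' @param ids identifiers; taken from rownames when omitted.
#' @param tol symmetry tolerance.
#' @return symmetric matrix classed `"similarity_matrix"`.
#' @export
similarity_matrix <- function(values, ids = rownames(values), tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(ids)) stop("similarity matrix requires identifiers")
  ids <- trimws(as.character(ids))
  if (anyDuplicated(ids)) stop("duplicate identifiers in similarity matrix")
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("similarity matrix contains missing values")
  if (max(abs(values - t(values))) > tol) stop("similarity matrix is not symmetric")
  if (min(values) < -tol || max(values) > 1 + tol) {
    stop("similarity entries must lie in [0, 1]")
  }
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  values[values > 1] <- 1
  dimnames(values) <- list(ids, ids)
  class(values) <- c("similarity_matrix", class(values))
  values
}

# internal: strip container class for plain matrix algebra
unclass_matrix <- function(x) {
  class(x) <- "matrix"
  attr(x, "class") <- NULL
  x
}
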