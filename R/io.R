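#' Read a circRNA-disease association table
#'
#' Two formats are supported. `"edge_list"` is a headerless-or-headered
#' two-column TSV/CSV of (circRNA id, disease id) rows; an optional third
#' label column is ignored. `"matrix"` is a labelled square table with a
#' header row of disease ids and a first column of circRNA ids, entries 0/1.
#' Identifier order is first-appearance order, so loading is deterministic.
#'
#' @param path file path.
#' @param format `"edge_list"` or `"matrix"`.
#' @param circ_ids,disease_ids optional identifier universes for the
#'   edge-list format; ids seen in the file but absent from a supplied
#'   universe raise an error, and ids in the universe with no edges get
#'   all-zero profiles.
#' @param sep field separator; `"\t"` by default, `","` for `.csv` paths.
#' @return an [association_matrix()].
#' @export
read_association <- function(path, format = c("edge_list", "matrix"),
                             circ_ids = NULL, disease_ids = NULL,
                             sep = default_sep(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("association file not found: %s", path))
  if (format == "matrix") {
    tab <- read_labelled_matrix(path, sep)
    return(association_matrix(tab))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, sep, fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2L)) {
    stop(sprintf("malformed edge list row at line %d of %s: expected >= 2 columns",
                 which(n_fields < 2L)[1L], path))
  }
  circ <- trimws(vapply(fields, `[[`, "", 1L))
  dis <- trimws(vapply(fields, `[[`, "", 2L))
  # tolerate a header row naming the columns
  if (length(circ) > 0L &&
      grepl("circ", circ[1L], ignore.case = TRUE) &&
      grepl("dis", dis[1L], ignore.case = TRUE)) {
    circ <- circ[-1L]
    dis <- dis[-1L]
  }
  dup <- duplicated(paste(circ, dis, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("%d duplicate association row(s) collapsed", sum(dup)))
    circ <- circ[!dup]
    dis <- dis[!dup]
  }
  if (is.null(circ_ids)) circ_ids <- unique(circ) else circ_ids <- trimws(circ_ids)
  if (is.null(disease_ids)) disease_ids <- unique(dis) else disease_ids <- trimws(disease_ids)
  if (length(circ) > 0L) {
    if (!all(circ %in% circ_ids)) {
      stop(sprintf("edge list circRNA id '%s' missing from declared universe",
                   setdiff(circ, circ_ids)[1L]))
    }
    if (!all(dis %in% disease_ids)) {
      stop(sprintf("edge list disease id '%s' missing from declared universe",
                   setdiff(dis, disease_ids)[1L]))
    }
  }
  A <- matrix(0, length(circ_ids), length(disease_ids),
              dimnames = list(circ_ids, disease_ids))
  if (length(circ) > 0L) A[cbind(match(circ, circ_ids), match(dis, disease_ids))] <- 1
  association_matrix(A)
}

#' Read an expression profile table
#'
#' Numeric TSV/CSV with circRNA ids in the first column and sample ids in the
#' header row.
#'
#' @inheritParams read_association
#' @return an [expression_profiles()] matrix.
#' @export
read_expression <- function(path, sep = default_sep(path)) {
  if (!file.exists(path)) stop(sprintf("expression file not found: %s", path))
  expression_profiles(read_labelled_matrix(path, sep))
}

#' Read a square similarity table
#'
#' Labelled square numeric TSV/CSV, e.g. a precomputed disease semantic or
#' phenotype similarity matrix.
#'
#' @inheritParams read_association
#' @return a [similarity_matrix()].
#' @export
read_similarity <- function(path, sep = default_sep(path)) {
  if (!file.exists(path)) stop(sprintf("similarity file not found: %s", path))
  similarity_matrix(read_labelled_matrix(path, sep))
}

#' Write a labelled matrix as TSV
#'
#' Writes a header row of column ids and a first column of row ids; the
#' format round-trips through the corresponding reader.
#'
#' @param x labelled matrix (any of the package's containers).
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  x <- unclass_matrix(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an association matrix as an edge list
#'
#' @param assoc an [association_matrix()].
#' @param path output path.
#' @export
write_edge_list <- function(assoc, path) {
  idx <- which(unclass_matrix(assoc) == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(circRNA = rownames(assoc)[idx[, 1L]],
                   disease = colnames(assoc)[idx[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict the three inputs to mutually consistent identifiers
#'
#' Diseases absent from the semantic similarity matrix are dropped from the
#' association matrix (mirroring the deletion of diseases with no matched
#' phenotype record); circRNAs absent from the expression set are kept, with
#' an all-zero expression similarity row so the integrated similarity falls
#' back to the GIP kernel. Expression rows for circRNAs outside the
#' association matrix are dropped.
#'
#' @param assoc [association_matrix()].
#' @param expr [expression_profiles()] or `NULL`.
#' @param dsim disease [similarity_matrix()] or `NULL`.
#' @return list with harmonized `assoc`, `expr`, `dsim` and a `dropped`
#'   report listing removed disease and expression ids.
#' @export
harmonize_ids <- function(assoc, expr = NULL, dsim = NULL) {
  dropped <- list(diseases = character(), expression_rows = character())
  if (!is.null(dsim)) {
    keep_d <- intersect(colnames(assoc), rownames(dsim))
    if (length(keep_d) == 0L) {
      stop("no disease identifiers shared between association matrix and disease similarity")
    }
    dropped$diseases <- setdiff(colnames(assoc), keep_d)
    assoc <- association_matrix(unclass_matrix(assoc)[, keep_d, drop = FALSE])
    dsim <- similarity_matrix(unclass_matrix(dsim)[keep_d, keep_d, drop = FALSE])
  }
  if (!is.null(expr)) {
    dropped$expression_rows <- setdiff(rownames(expr), rownames(assoc))
    keep_c <- intersect(rownames(expr), rownames(assoc))
    expr <- if (length(keep_c) > 0L) {
      expression_profiles(unclass_matrix(expr)[keep_c, , drop = FALSE])
    } else NULL
  }
  list(assoc = assoc, expr = expr, dsim = dsim, dropped = dropped)
}

default_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# internal: labelled numeric table -> matrix, with cell-level error reporting
read_labelled_matrix <- function(path, sep) {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "",
                           fileEncoding = "UTF-8")
  m <- as.matrix(tab)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- which(is.na(num) | m == "")
  if (length(bad) > 0L) {
    b <- bad[1L]
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s' in %s",
                 rownames(m)[(b - 1L) %% nrow(m) + 1L],
                 colnames(m)[(b - 1L) %/% nrow(m) + 1L], path))
  }
  num
}
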