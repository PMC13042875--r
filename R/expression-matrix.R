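#' Expression matrix container
#'
#' Light-weight genes x cells container used by every scoring stage. Values
#' are non-negative (raw counts or log-normalized; the `normalized` flag
#' records which), gene and cell identifiers are unique, and `cell_meta`
#' carries one row per cell (sample / group / timepoint labels, plus a
#' lobule-layer column for zonation references).
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, genes in rows and
#'   cells in columns, with unique dimnames.
#' @param cell_meta data.frame with one row per cell; a `cell_id` column is
#'   added from the matrix colnames when absent.
#' @param normalized logical flag; `TRUE` marks log-normalized values.
#' @return an object of class `expression_matrix` with elements `values`,
#'   `cell_meta`, `normalized`.
#' @export
expression_matrix <- function(values, cell_meta = NULL, normalized = FALSE) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(values))) stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(values))) stop("cell identifiers must be unique")
  if (min(values) < 0) stop("expression values must be non-negative")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(values), stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta)) {
    if (nrow(cell_meta) != ncol(values)) {
      stop("`cell_meta` must have one row per cell")
    }
    cell_meta <- cbind(cell_id = colnames(values), cell_meta)
  }
  if (nrow(cell_meta) != ncol(values) ||
      !identical(as.character(cell_meta$cell_id), colnames(values))) {
    stop("`cell_meta` rows must align 1:1 with matrix columns")
  }
  rownames(cell_meta) <- NULL
  structure(
    list(values = values, cell_meta = cell_meta, normalized = isTRUE(normalized)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d cells (%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "log-normalized" else "raw counts"
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of gene names.
#' @export
genes <- function(x) rownames(x$values)

#' Cell identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of cell names.
#' @export
cells <- function(x) colnames(x$values)

#' Log-normalize raw counts
#'
#' Scales every cell to a total of 10,000 counts and applies `log(1 + x)`,
#' the standard library-size normalization for droplet single-cell data.
#' Refuses cells with zero total counts (naming them) and refuses to
#' re-normalize an already normalized matrix.
#'
#' @param expr an `expression_matrix` of raw counts.
#' @param scale_factor per-cell target total before `log1p` (default 1e4).
#' @return an `expression_matrix` flagged as log-normalized.
#' @export
normalize_expression <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$normalized) {
    stop("matrix is already log-normalized; re-normalization is not allowed")
  }
  totals <- Matrix::colSums(expr$values)
  if (any(totals == 0)) {
    bad <- colnames(expr$values)[totals == 0]
    stop(
      "cells with zero total counts cannot be normalized: ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  v <- expr$values
  if (inherits(v, "sparseMatrix")) {
    v <- Matrix::t(Matrix::t(v) * (scale_factor / totals))
    v@x <- log1p(v@x)
  } else {
    v <- log1p(t(t(v) * (scale_factor / totals)))
  }
  expression_matrix(v, expr$cell_meta, normalized = TRUE)
}

#' Subset an expression matrix by cells
#' @param expr an `expression_matrix`.
#' @param cell_ids character vector of cell identifiers to keep.
#' @return an `expression_matrix` restricted to those cells, in that order.
#' @export
subset_cells <- function(expr, cell_ids) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing <- setdiff(cell_ids, colnames(expr$values))
  if (length(missing) > 0) {
    stop("unknown cells: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  idx <- match(cell_ids, colnames(expr$values))
  expression_matrix(
    expr$values[, idx, drop = FALSE],
    expr$cell_meta[idx, , drop = FALSE],
    normalized = expr$normalized
  )
}
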