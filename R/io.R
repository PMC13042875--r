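#' Write an expression matrix as Matrix Market + metadata TSVs
#'
#' Writes `matrix.mtx` (genes as rows), `genes.tsv` (one gene per line) and
#' `cells.tsv` (the cell metadata, tab-separated with header) into `dir`.
#'
#' @param expr an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(expr, dir) {
  stopifnot(inherits(expr, "expression_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(expr$values, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr$values), file.path(dir, "genes.tsv"))
  utils::write.table(expr$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(if (expr$normalized) "log-normalized" else "counts",
             file.path(dir, "values.flag"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  g <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  dimnames(m) <- list(g, meta$cell_id)
  flag_file <- file.path(dir, "values.flag")
  normalized <- file.exists(flag_file) &&
    identical(readLines(flag_file), "log-normalized")
  expression_matrix(methods::as(m, "CsparseMatrix"), meta,
                    normalized = normalized)
}

#' Read gene signatures from a GMT file
#'
#' @param path GMT file (tab-separated: name, description, genes...).
#' @return named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_signature(f[1], f[-(1:2)])
  })
  stats::setNames(sigs, vapply(sigs, `[[`, character(1), "name"))
}

#' Write gene signatures to a GMT file
#'
#' @param signatures a [gene_signature()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Co-IP-MS protein table from TSV
#'
#' Expects the documented header: `protein_id`, `unique_peptides`, `score`,
#' `coverage_pct`, `intensity_exp`, `intensity_igg_1..n`, `ibaq_exp`,
#' `ibaq_igg`, `contaminant`.
#'
#' @param path TSV file.
#' @param experiment experiment label (default taken from the file name).
#' @return a [protein_table()].
#' @export
read_protein_table <- function(path, experiment = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$contaminant <- as.logical(df$contaminant)
  protein_table(df, experiment = experiment)
}

#' Write a Co-IP-MS protein table to TSV
#'
#' @param table a [protein_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read time-series profiles from TSV
#'
#' Rows are series, columns samples (in order); the first column holds the
#' series name.
#'
#' @param path TSV file.
#' @return named matrix, series x samples.
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write time-series profiles to TSV
#'
#' @param profiles named matrix (series x samples) or named list of series.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  df <- data.frame(name = rownames(profiles), profiles, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
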