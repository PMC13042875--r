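#' Soft-threshold co-expression adjacency
#'
#' Unsigned weighted-network adjacency between genes:
#' `a_ij = |Pearson cor(g_i, g_j)|^beta`, computed across cells, with the
#' diagonal set to 0 by convention (so connectivity sums exclude self
#' edges). Zero-variance genes are dropped with a warning.
#'
#' @param expr an [expression_matrix()].
#' @param genes genes to include (default all).
#' @param beta soft-threshold power (default 6, the unsigned convention).
#' @return symmetric genes x genes adjacency matrix with zero diagonal.
#' @export
soft_adjacency <- function(expr, genes = NULL, beta = 6) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 3) stop("at least 3 cells are required")
  if (is.null(genes)) genes <- rownames(expr$values)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing) > 0) {
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "))
  }
  X <- t(as.matrix(expr$values[genes, , drop = FALSE]))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance gene(s) dropped", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("fewer than 2 genes survive the variance filter")
  a <- abs(stats::cor(X))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' Neighborhood-sharing similarity of a weighted network:
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu`, and `TOM_ii = 1`.
#'
#' @param adjacency square symmetric matrix with values in \[0, 1\] and a
#'   zero diagonal (as produced by [soft_adjacency()]).
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-9) stop("adjacency must be symmetric")
  if (min(a) < 0 || max(a) > 1) stop("adjacency values must lie in [0, 1]")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(a)
  # with a zero diagonal, (a %*% a)[i, j] = sum over u != i, j of a_iu a_uj
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module eigengene and eigengene-based connectivity (kME)
#'
#' The module eigengene is the first right-singular vector over cells of
#' the z-scored module submatrix (the module's first principal component),
#' normalized to unit length and sign-oriented so that its average
#' correlation with the module genes is non-negative. kME is the Pearson
#' correlation of every gene in the matrix with the eigengene.
#'
#' @param expr an [expression_matrix()].
#' @param module_genes at least 2 genes present in the matrix;
#'   zero-variance module genes are dropped with a warning.
#' @return list with `eigengene` (named per-cell vector, unit norm) and
#'   `kme` (named vector over all matrix genes; `NA` for zero-variance
#'   genes).
#' @export
module_eigengene_kme <- function(expr, module_genes) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing <- setdiff(module_genes, genes(expr))
  if (length(missing) > 0) {
    stop("module genes absent from the matrix: ", paste(missing, collapse = ", "))
  }
  if (length(module_genes) < 2) stop("a module needs at least 2 genes")
  X <- t(as.matrix(expr$values[module_genes, , drop = FALSE]))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance module gene(s) dropped", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("all module genes have zero variance")
  Z <- scale(X)
  sv <- svd(Z, nu = 1, nv = 0)
  eigengene <- sv$u[, 1]
  if (mean(stats::cor(Z, eigengene)) < 0) eigengene <- -eigengene
  names(eigengene) <- cells(expr)
  all_expr <- t(as.matrix(expr$values))
  kme <- suppressWarnings(as.numeric(stats::cor(all_expr, eigengene)))
  names(kme) <- genes(expr)
  list(eigengene = eigengene, kme = kme)
}

#' Build a network module around a gene set
#'
#' Convenience constructor combining [soft_adjacency()],
#' [topological_overlap()] and [module_eigengene_kme()] for one module.
#'
#' @param expr an [expression_matrix()].
#' @param module_genes the module's genes.
#' @param name module name.
#' @param anchor optional anchor gene.
#' @param beta soft-threshold power (default 6).
#' @return a `network_module`: list with `name`, `genes`, `eigengene`,
#'   `kme` (module genes), `tom` (module genes x module genes), `anchor`.
#' @export
build_network_module <- function(expr, module_genes, name = "module",
                                 anchor = NULL, beta = 6) {
  adj <- soft_adjacency(expr, module_genes, beta = beta)
  kept <- rownames(adj)
  tom <- topological_overlap(adj)
  ek <- module_eigengene_kme(expr, kept)
  structure(
    list(
      name = name, genes = kept, eigengene = ek$eigengene,
      kme = ek$kme[kept], tom = tom, anchor = anchor
    ),
    class = "network_module"
  )
}

#' Extract the anchor-centric sub-network of a module
#'
#' Applies the two-stage hub filter: keep module genes with
#' `kME > kme_min` (strict) that are directly connected to the anchor with
#' TOM weight strictly above `tom_min`; the anchor itself is always
#' retained. Also reports the anchor's kME and its rank among the module
#' genes by decreasing kME (ties broken lexicographically), and flags the
#' `top_n` genes by kME for display.
#'
#' @param module a `network_module` (needs `genes`, `kme`, `tom`).
#' @param anchor anchor gene; must belong to the module.
#' @param kme_min strict kME threshold (default 0.25).
#' @param tom_min strict TOM-weight threshold to the anchor (default 0.025).
#' @param top_n number of top-kME genes to flag (default 10).
#' @return a `network_module` restricted to the surviving genes, with
#'   attributes `anchor_kme`, `anchor_rank`, `top_hub_genes` and a
#'   `nodes` data.frame (gene, kme, tom_to_anchor, rank, is_hub).
#' @export
extract_anchor_subnetwork <- function(module, anchor, kme_min = 0.25,
                                      tom_min = 0.025, top_n = 10) {
  stopifnot(inherits(module, "network_module"))
  if (!anchor %in% module$genes) stop("anchor gene is not in the module: ", anchor)
  kme <- module$kme[module$genes]
  tom_anchor <- module$tom[anchor, module$genes]
  keep <- (kme > kme_min) & (tom_anchor > tom_min)
  keep[anchor] <- TRUE
  kept <- module$genes[keep]

  # kME ranking with lexicographic tie-break
  ord <- order(-kme, module$genes)
  rank_all <- stats::setNames(match(module$genes, module$genes[ord]), module$genes)
  hubs <- module$genes[ord][seq_len(min(top_n, length(ord)))]

  nodes <- data.frame(
    gene = kept,
    kme = kme[kept],
    tom_to_anchor = tom_anchor[kept],
    rank = rank_all[kept],
    is_hub = kept %in% hubs,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      name = paste0(module$name, ":", anchor), genes = kept,
      eigengene = module$eigengene, kme = kme[kept],
      tom = module$tom[kept, kept, drop = FALSE], anchor = anchor
    ),
    class = "network_module",
    anchor_kme = unname(kme[anchor]),
    anchor_rank = unname(rank_all[anchor]),
    top_hub_genes = hubs,
    nodes = nodes
  )
}
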