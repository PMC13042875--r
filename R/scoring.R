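#' Gene signature
#'
#' @param name signature name.
#' @param genes character vector of unique gene identifiers (non-empty).
#' @return list of class `gene_signature`.
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("a gene signature must contain at least one gene")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Gene-set module score with binned expression-matched controls
#'
#' Scores each cell for a signature by contrasting the mean log-normalized
#' expression of the signature genes against a pooled control set drawn
#' from expression-matched bins: all genes are ranked by their average
#' expression across cells and split into `n_bins` equal-frequency bins;
#' for every signature gene, `n_ctrl` control genes are sampled from its
#' bin (without replacement, falling back to with-replacement when the bin
#' is smaller than `n_ctrl`). The per-cell score is
#' mean(signature genes) - mean(pooled controls).
#'
#' @param expr log-normalized [expression_matrix()].
#' @param signature a [gene_signature()]; genes absent from the matrix are
#'   dropped with a warning, an empty intersection is an error.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for the control sampling.
#' @return numeric per-cell score vector named by cell.
#' @export
module_score <- function(expr, signature, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(signature, "gene_signature"))
  if (!expr$normalized) stop("module_score expects a log-normalized matrix")
  sig <- intersect(signature$genes, genes(expr))
  if (length(sig) == 0) {
    stop("no signature gene is present in the expression matrix")
  }
  if (length(sig) < length(signature$genes)) {
    warning(sprintf(
      "%d signature gene(s) absent from the matrix were dropped",
      length(signature$genes) - length(sig)
    ))
  }
  avg <- Matrix::rowMeans(expr$values)
  # equal-frequency bins over average expression (ties broken by rank order)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk * n_bins / length(rk))
  names(bin) <- names(avg)
  ctrl <- withr::with_seed(as.integer(seed), {
    unlist(lapply(sig, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(expr$values[sig, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr$values[ctrl, , drop = FALSE])
  as.numeric(sig_mean - ctrl_mean) |> stats::setNames(cells(expr))
}

#' Classify cycling cells from a cell-cycle score
#'
#' A cell is called cycling when its score lies strictly above the mean
#' score plus three sample standard deviations (n-1 denominator). With
#' all-identical scores the threshold equals the mean and no cell is
#' flagged.
#'
#' @param scores numeric per-cell score vector (length >= 2).
#' @param n_sd number of standard deviations above the mean (default 3).
#' @return logical vector, `TRUE` for cycling cells; the threshold is
#'   attached as attribute `threshold`.
#' @export
classify_cycling <- function(scores, n_sd = 3) {
  if (length(scores) < 2) stop("at least 2 cells are required")
  thr <- mean(scores) + n_sd * stats::sd(scores)
  structure(scores > thr, threshold = thr, names = names(scores))
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two disjoint cell
#' groups on log-normalized values: exact by enumeration when the smaller
#' group has at most `exact_max` cells and there are no ties, normal
#' approximation with tie correction otherwise. Fold changes revert the
#' log1p transform before averaging and add a pseudocount of 1:
#' `log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))`. P-values are
#' Benjamini-Hochberg adjusted across all tested genes.
#'
#' @param expr log-normalized [expression_matrix()].
#' @param group_a,group_b disjoint cell-id vectors, each with >= 2 cells.
#' @param min_pct optional detection-fraction pre-filter: only test genes
#'   detected in at least this fraction of either group (default 0, off).
#' @param logfc_min optional absolute log2 fold-change pre-filter
#'   (default 0, off).
#' @param exact_max largest min-group size for the exact test (default 10).
#' @return data.frame with columns `gene`, `log2_fc`, `p_value`, `adj_p`,
#'   `pct_a`, `pct_b`, ordered by `p_value`.
#' @export
rank_sum_de <- function(expr, group_a, group_b, min_pct = 0, logfc_min = 0,
                        exact_max = 10) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!expr$normalized) stop("rank_sum_de expects a log-normalized matrix")
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need at least 2 cells")
  }
  if (length(intersect(group_a, group_b)) > 0) stop("cell groups must be disjoint")
  a <- as.matrix(expr$values[, match(group_a, cells(expr)), drop = FALSE])
  b <- as.matrix(expr$values[, match(group_b, cells(expr)), drop = FALSE])
  if (anyNA(a) || anyNA(b)) stop("unknown cells in group_a/group_b")

  pct_a <- rowMeans(a > 0)
  pct_b <- rowMeans(b > 0)
  log2_fc <- log2((rowMeans(expm1(a)) + 1) / (rowMeans(expm1(b)) + 1))
  keep <- (pmax(pct_a, pct_b) >= min_pct) & (abs(log2_fc) >= logfc_min)
  idx <- which(keep)
  n_min <- min(ncol(a), ncol(b))
  p <- vapply(idx, function(i) {
    x <- a[i, ]; y <- b[i, ]
    ties <- anyDuplicated(c(x, y)) > 0
    if (!ties && n_min <= exact_max) {
      stats::wilcox.test(x, y, exact = TRUE)$p.value
    } else {
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    }
  }, numeric(1))
  out <- data.frame(
    gene = genes(expr)[idx],
    log2_fc = log2_fc[idx],
    p_value = p,
    adj_p = stats::p.adjust(p, method = "BH"),
    pct_a = pct_a[idx],
    pct_b = pct_b[idx],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$p_value), , drop = FALSE]
}

# Fuzzy c-means on rows of X (Euclidean, fuzzifier m), seeded random
# membership initialization; stops when the largest membership change
# drops below `tol` or after `max_iter` iterations.
.fuzzy_cmeans <- function(X, k, m = 2, seed = 1L, tol = 1e-6, max_iter = 300L) {
  n <- nrow(X)
  u <- withr::with_seed(as.integer(seed), {
    u0 <- matrix(stats::runif(n * k), n, k)
    u0 / rowSums(u0)
  })
  for (iter in seq_len(max_iter)) {
    um <- u^m
    centers <- (t(um) %*% X) / colSums(um)
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  um <- u^m
  centers <- (t(um) %*% X) / colSums(um)
  list(membership = u, centers = centers, iterations = iter)
}

#' Temporally upregulated genes by fuzzy c-means clustering
#'
#' Clusters z-scored per-gene temporal profiles with fuzzy c-means
#' (Euclidean distance, fuzzifier `m`, seeded initialization) and returns
#' the genes whose maximal membership falls in a "transplant-upregulated"
#' cluster: one whose centroid at both early post-transplantation
#' timepoints exceeds its centroid at the baseline and at the late
#' timepoint. Constant profiles are dropped with a warning before
#' z-scoring.
#'
#' @param sample_profiles genes x timepoints numeric matrix of per-sample
#'   mean expression, with timepoint colnames.
#' @param k number of clusters (>= 1).
#' @param m fuzzifier (default 2).
#' @param seed integer seed for the membership initialization.
#' @param baseline,early,late timepoint names defining the up-criterion
#'   (defaults follow the 8-sample transplantation design: baseline
#'   `R0_0W`, early `R1_1W`/`R1_3W`, late `R1_12W`).
#' @return a [gene_signature()] named `temporal_up`; cluster memberships,
#'   centroids and the indices of upregulated clusters are attached as
#'   attributes `membership`, `centers`, `up_clusters`.
#' @export
temporal_up_genes <- function(sample_profiles, k, m = 2, seed = 1L,
                              baseline = "R0_0W",
                              early = c("R1_1W", "R1_3W"),
                              late = "R1_12W") {
  if (ncol(sample_profiles) < 3) stop("at least 3 timepoints are required")
  if (k < 1) stop("k must be >= 1")
  need <- c(baseline, early, late)
  if (!all(need %in% colnames(sample_profiles))) {
    stop("profile columns must include: ", paste(need, collapse = ", "))
  }
  sds <- apply(sample_profiles, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant profile(s) dropped before z-scoring", sum(sds == 0)))
    sample_profiles <- sample_profiles[sds > 0, , drop = FALSE]
  }
  if (nrow(sample_profiles) == 0) {
    sig <- structure(list(name = "temporal_up", genes = character(0)),
                     class = "gene_signature")
    return(sig)
  }
  Z <- t(scale(t(sample_profiles)))
  fit <- .fuzzy_cmeans(Z, k = k, m = m, seed = seed)
  centers <- fit$centers
  up <- which(vapply(seq_len(k), function(j) {
    all(centers[j, early] > centers[j, baseline]) &&
      all(centers[j, early] > centers[j, late])
  }, logical(1)))
  assign <- max.col(fit$membership, ties.method = "first")
  genes_up <- rownames(Z)[assign %in% up]
  sig <- if (length(genes_up) > 0) {
    gene_signature("temporal_up", genes_up)
  } else {
    structure(list(name = "temporal_up", genes = character(0)),
              class = "gene_signature")
  }
  attr(sig, "membership") <- fit$membership
  attr(sig, "centers") <- centers
  attr(sig, "up_clusters") <- up
  sig
}

#' Derive the reprogrammed-hepatocyte signature (ARS)
#'
#' The signature is the union of (1) genes significantly upregulated in the
#' differential-expression result (`log2_fc > lfc_min` and
#' `adj_p < alpha`, both strict) and (2) the temporally upregulated gene
#' set. An empty union is allowed but warned about.
#'
#' @param de a [rank_sum_de()] result.
#' @param temporal a [gene_signature()] of temporally upregulated genes.
#' @param lfc_min strict lower bound on log2 fold change (default 1).
#' @param alpha strict upper bound on the BH-adjusted p-value (default 0.05).
#' @return a [gene_signature()] named `ARS`; the two constituent sets are
#'   attached as attributes `deg_genes` and `temporal_genes`.
#' @export
derive_ars <- function(de, temporal, lfc_min = 1, alpha = 0.05) {
  stopifnot(is.data.frame(de), inherits(temporal, "gene_signature"))
  deg <- de$gene[de$log2_fc > lfc_min & de$adj_p < alpha]
  ars <- union(deg, temporal$genes)
  if (length(ars) == 0) {
    warning("the derived signature is empty")
    sig <- structure(list(name = "ARS", genes = character(0)),
                     class = "gene_signature")
  } else {
    sig <- gene_signature("ARS", ars)
  }
  attr(sig, "deg_genes") <- deg
  attr(sig, "temporal_genes") <- temporal$genes
  sig
}
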