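#' Zone grouping of lobule layers
#'
#' Fixed total map from the 8 lobule layers to the three histological
#' zones: layers 1-3 are Zone3 (pericentral), layers 4-6 Zone2
#' (intermediate), layers 7-8 Zone1 (periportal).
#'
#' @param layer integer vector with values in 1..8.
#' @return character vector of zone labels.
#' @export
layer_to_zone <- function(layer) {
  if (any(!layer %in% 1:8)) stop("layers must be integers in 1..8")
  map <- c("Zone3", "Zone3", "Zone3", "Zone2", "Zone2", "Zone2", "Zone1", "Zone1")
  map[layer]
}

# cells x features matrix for model input; errors on missing features
.feature_matrix <- function(expr, features) {
  missing <- setdiff(features, genes(expr))
  if (length(missing) > 0) {
    stop("features absent from the matrix: ", paste(missing, collapse = ", "))
  }
  t(as.matrix(expr$values[features, , drop = FALSE]))
}

#' Fit a PLSR zonation coordinate
#'
#' Projects z-scored marker expression onto latent components predictive of
#' the (centered) lobule-layer index by the NIPALS iterative algorithm,
#' giving every cell a continuous porto-central coordinate on the layer
#' scale. Zero-variance markers are dropped with a warning.
#'
#' @param ref a `layered_reference` from [simulate_zonated_reference()] or
#'   an equivalent list with `expression` and `layer`.
#' @param markers marker genes used as predictors (default the 18
#'   candidates); all must be present in the reference.
#' @param n_components number of latent components (default 2).
#' @return a `zonation_model` of kind `"plsr"` holding feature scaling,
#'   regression coefficients and the training layer mean.
#' @export
fit_plsr_zonation <- function(ref, markers = zonation_marker_candidates(),
                              n_components = 2) {
  expr <- ref$expression
  missing <- setdiff(markers, genes(expr))
  if (length(missing) > 0) {
    stop("markers absent from the reference: ", paste(missing, collapse = ", "))
  }
  X <- .feature_matrix(expr, markers)
  y <- as.numeric(ref$layer)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance marker(s) dropped", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("all markers have zero variance")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Xz <- scale(X, center = mu, scale = sdv)
  y_bar <- mean(y)
  yc <- y - y_bar

  p <- ncol(Xz)
  A <- min(n_components, p)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  q <- numeric(A)
  Xr <- Xz
  yr <- yc
  for (h in seq_len(A)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- h - 1L; break }
    w <- w / nw
    t_h <- Xr %*% w
    tt <- sum(t_h^2)
    p_h <- crossprod(Xr, t_h) / tt
    q_h <- sum(yr * t_h) / tt
    Xr <- Xr - t_h %*% t(p_h)
    yr <- yr - q_h * t_h
    W[, h] <- w; P[, h] <- p_h; q[h] <- q_h
  }
  if (A == 0) stop("no predictive latent component could be extracted")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  coef <- W %*% solve(t(P) %*% W, q)

  structure(
    list(
      kind = "plsr", features = colnames(X), center = mu, scale = sdv,
      coef = as.numeric(coef), intercept = y_bar, n_components = A
    ),
    class = "zonation_model"
  )
}

#' @export
print.zonation_model <- function(x, ...) {
  cat(sprintf("<zonation_model: %s> %d feature(s)", x$kind, length(x$features)))
  if (!is.null(x$cv_auc)) cat(sprintf(", cv_auc = %.3f", x$cv_auc))
  cat("\n")
  invisible(x)
}

#' Per-cell zonation scores and per-sample dispersion
#'
#' Applies a fitted PLSR zonation model: each cell receives a predicted
#' layer coordinate clamped to \[1, 8\], and each sample the standard
#' deviation of its cells' coordinates (the heterogeneity readout; samples
#' with fewer than 2 cells report `NA`).
#'
#' @param model a `zonation_model` of kind `"plsr"`.
#' @param expr an [expression_matrix()] containing the model features and a
#'   `sample` column in its cell_meta.
#' @return list with `score` (named per-cell coordinates) and `dispersion`
#'   (named per-sample sd).
#' @export
zonation_scores <- function(model, expr) {
  stopifnot(inherits(model, "zonation_model"))
  if (model$kind != "plsr") stop("zonation_scores requires a PLSR model")
  X <- .feature_matrix(expr, model$features)
  Xz <- scale(X, center = model$center, scale = model$scale)
  score <- as.numeric(model$intercept + Xz %*% model$coef)
  score <- pmin(pmax(score, 1), 8)
  names(score) <- cells(expr)
  samples <- expr$cell_meta$sample
  if (is.null(samples)) samples <- rep("all", length(score))
  dispersion <- vapply(split(score, samples), function(s) {
    if (length(s) < 2) NA_real_ else stats::sd(s)
  }, numeric(1))
  list(score = score, dispersion = dispersion)
}

# rank-based AUC of `x` for positives `pos` (Mann-Whitney formulation)
.rank_auc <- function(x, pos) {
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(x)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# seeded stratified fold assignment on cells sorted by identifier, so the
# split is invariant to input ordering
.stratified_folds <- function(cell_ids, strata, n_folds, seed) {
  ord <- order(cell_ids)
  fold <- integer(length(cell_ids))
  withr::with_seed(as.integer(seed), {
    for (s in unique(strata[ord])) {
      idx <- ord[strata[ord] == s]
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

.xgb_params <- function(nthread = 1L) {
  list(
    objective = "multi:softprob", num_class = 8L,
    max_depth = 4L, eta = 0.3, nthread = nthread
  )
}

#' Select zonation marker features by attribution ranking
#'
#' Fits a preliminary gradient-boosted multiclass classifier of lobule
#' layer on all candidate markers and ranks features by mean absolute
#' attribution over the reference cells: tree-based additive (SHAP)
#' attributions by default, or seeded permutation importance (drop in
#' held-in multiclass log-likelihood when a feature column is permuted).
#'
#' @param ref a `layered_reference`.
#' @param candidates candidate marker genes (default the 18 candidates).
#' @param k number of features to keep (default 4).
#' @param seed integer seed (permutation attribution and model fitting).
#' @param attribution `"shap"` (default) or `"permutation"`.
#' @param nrounds boosting rounds of the preliminary model (default 40).
#' @return character vector of the top-`k` features, ordered by decreasing
#'   attribution; the full ranking is attached as attribute `importance`.
#' @export
select_marker_features <- function(ref, candidates = zonation_marker_candidates(),
                                   k = 4, seed = 1L, attribution = c("shap", "permutation"),
                                   nrounds = 40) {
  attribution <- match.arg(attribution)
  expr <- ref$expression
  missing <- setdiff(candidates, genes(expr))
  if (length(missing) > 0) {
    stop("candidates absent from the reference: ", paste(missing, collapse = ", "))
  }
  if (k > length(candidates)) stop("k cannot exceed the number of candidates")
  if (length(unique(ref$layer)) < 2) {
    stop("reference must contain more than one layer")
  }
  X <- .feature_matrix(expr, candidates)
  label <- as.integer(ref$layer) - 1L
  bst <- withr::with_seed(as.integer(seed), {
    xgboost::xgb.train(
      params = .xgb_params(), nrounds = nrounds,
      data = xgboost::xgb.DMatrix(X, label = label)
    )
  })
  imp <- if (attribution == "shap") {
    contrib <- predict(bst, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
    # cells x classes x (features + bias): average |contribution| over
    # cells and classes, dropping the bias column
    m <- apply(abs(contrib), 3, mean)[seq_along(candidates)]
    stats::setNames(m, candidates)
  } else {
    probs <- predict(bst, xgboost::xgb.DMatrix(X))
    base_ll <- mean(log(pmax(probs[cbind(seq_along(label), label + 1L)], 1e-15)))
    withr::with_seed(as.integer(seed) + 1L, {
      vapply(stats::setNames(seq_along(candidates), candidates), function(j) {
        Xp <- X
        Xp[, j] <- sample(Xp[, j])
        pp <- predict(bst, xgboost::xgb.DMatrix(Xp))
        base_ll - mean(log(pmax(pp[cbind(seq_along(label), label + 1L)], 1e-15)))
      }, numeric(1))
    })
  }
  ranked <- names(sort(imp, decreasing = TRUE))
  structure(ranked[seq_len(k)], importance = sort(imp, decreasing = TRUE))
}

#' Train the 8-layer zonation classifier
#'
#' Gradient-boosted multiclass classifier of lobule layer on the selected
#' feature genes, with per-class sample weights `N / (8 * N_c)` to address
#' class imbalance. Performance is estimated by seeded stratified k-fold
#' cross-validation; `cv_auc` is the mean over folds of the macro
#' one-vs-rest AUC. The returned model is refit on all cells.
#'
#' @param ref a `layered_reference` with every layer 1..8 present and at
#'   least `n_folds` cells per layer.
#' @param features feature genes (e.g. from [select_marker_features()]).
#' @param n_folds cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param nrounds boosting rounds (default 60).
#' @return a `zonation_model` of kind `"layer-classifier"` with elements
#'   `booster`, `cv_auc` and `training_summary` (per-fold macro AUC).
#' @export
train_layer_classifier <- function(ref, features, n_folds = 5, seed = 1L,
                                   nrounds = 60) {
  expr <- ref$expression
  layer <- as.integer(ref$layer)
  if (!all(1:8 %in% layer)) {
    stop("every layer 1..8 must be present in the training reference")
  }
  if (min(table(layer)) < n_folds) {
    stop("each layer needs at least `n_folds` cells")
  }
  X <- .feature_matrix(expr, features)
  label <- layer - 1L
  n <- length(label)
  tab <- table(factor(layer, levels = 1:8))
  w_class <- n / (8 * as.numeric(tab))
  names(w_class) <- names(tab)
  weight <- w_class[as.character(layer)]

  fold <- .stratified_folds(cells(expr), layer, n_folds, seed)
  fold_auc <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    bst <- withr::with_seed(as.integer(seed) + f, {
      xgboost::xgb.train(
        params = .xgb_params(), nrounds = nrounds,
        data = xgboost::xgb.DMatrix(
          X[tr, , drop = FALSE], label = label[tr], weight = weight[tr]
        )
      )
    })
    probs <- predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
    y_te <- label[!tr]
    aucs <- vapply(0:7, function(cl) .rank_auc(probs[, cl + 1L], y_te == cl),
                   numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))

  bst_full <- withr::with_seed(as.integer(seed), {
    xgboost::xgb.train(
      params = .xgb_params(), nrounds = nrounds,
      data = xgboost::xgb.DMatrix(X, label = label, weight = weight)
    )
  })
  structure(
    list(
      kind = "layer-classifier", features = features, booster = bst_full,
      class_weights = w_class, cv_auc = mean(fold_auc),
      training_summary = data.frame(fold = seq_len(n_folds), macro_auc = fold_auc)
    ),
    class = "zonation_model"
  )
}

#' Predict lobule layers and zones
#'
#' Applies a trained layer classifier: each cell's layer is the argmax of
#' the class probabilities (ties resolved to the lowest layer index) and
#' its zone follows the fixed grouping [layer_to_zone()].
#'
#' @param model a `zonation_model` of kind `"layer-classifier"`.
#' @param expr an [expression_matrix()] containing the model features.
#' @return a `zone_assignment` data.frame with columns `cell_id`, `sample`,
#'   `layer`, `zone`; the cells x 8 probability matrix is attached as
#'   attribute `probabilities`.
#' @export
predict_layers_and_zones <- function(model, expr) {
  stopifnot(inherits(model, "zonation_model"))
  if (model$kind != "layer-classifier") {
    stop("predict_layers_and_zones requires a layer classifier")
  }
  X <- .feature_matrix(expr, model$features)
  probs <- predict(model$booster, xgboost::xgb.DMatrix(X))
  probs <- probs / rowSums(probs)
  colnames(probs) <- paste0("L", 1:8)
  layer <- max.col(probs, ties.method = "first")
  out <- data.frame(
    cell_id = cells(expr),
    sample = expr$cell_meta$sample,
    layer = layer,
    zone = layer_to_zone(layer),
    stringsAsFactors = FALSE
  )
  class(out) <- c("zone_assignment", "data.frame")
  attr(out, "probabilities") <- probs
  out
}

#' Zone-proportion time series
#'
#' Per-sample fraction of cells assigned to each zone, ordered by the given
#' sample order; zones absent from a sample report 0.
#'
#' @param assignments a `zone_assignment` (or data.frame with `sample` and
#'   `zone` columns); every sample must have at least one cell.
#' @param sample_order ordered sample names; unknown names are an error.
#' @return 3 x n_samples numeric matrix with rows Zone1, Zone2, Zone3 and
#'   columns in `sample_order` (each column sums to 1).
#' @export
zone_proportion_series <- function(assignments, sample_order) {
  stopifnot(all(c("sample", "zone") %in% names(assignments)))
  unknown <- setdiff(sample_order, unique(assignments$sample))
  if (length(unknown) > 0) {
    stop("unknown sample(s) in order list: ", paste(unknown, collapse = ", "))
  }
  zones <- c("Zone1", "Zone2", "Zone3")
  out <- vapply(sample_order, function(s) {
    z <- assignments$zone[assignments$sample == s]
    as.numeric(table(factor(z, levels = zones)) / length(z))
  }, numeric(3))
  rownames(out) <- zones
  out
}
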