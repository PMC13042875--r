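#' Dynamic time warping distance
#'
#' Classic DTW with absolute-difference local cost and the symmetric step
#' pattern: `D(i,j) = |a_i - b_j| + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`
#' with cumulative first row/column; the distance is `D(m, n)`. No window
#' constraint and no path-length normalization. With `z_normalize = TRUE`
#' (the default) both series are z-scored first; a zero-variance series is
#' mapped to all-zeros with a warning.
#'
#' @param a,b non-empty numeric series.
#' @param z_normalize z-score each series before alignment (default TRUE).
#' @return non-negative alignment distance.
#' @export
dtw_distance <- function(a, b, z_normalize = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("series must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("series must not contain missing values")
  if (z_normalize) {
    a <- .z_norm(a)
    b <- .z_norm(b)
  }
  m <- length(a); n <- length(b)
  cost <- abs(outer(a, b, "-"))
  D <- matrix(0, m, n)
  D[1, 1] <- cost[1, 1]
  if (m > 1) for (i in 2:m) D[i, 1] <- D[i - 1, 1] + cost[i, 1]
  if (n > 1) for (j in 2:n) D[1, j] <- D[1, j - 1] + cost[1, j]
  if (m > 1 && n > 1) {
    for (i in 2:m) {
      for (j in 2:n) {
        D[i, j] <- cost[i, j] + min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
      }
    }
  }
  D[m, n]
}

.z_norm <- function(x) {
  s <- stats::sd(x)
  if (length(x) < 2 || s == 0) {
    warning("zero-variance series z-scored to all-zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Rank pathways by temporal coupling to zonation dynamics
#'
#' For every pathway-activity profile, computes the DTW distance to each of
#' the three zone-proportion series (all series z-normalized first, so
#' proportions and activity scores are comparable), aggregates the three
#' distances, and ranks pathways ascending by aggregate (smaller distance =
#' stronger coupling; ties broken lexicographically by pathway name).
#'
#' The default aggregate is the minimum of the three per-zone distances —
#' the distance to the pathway's best-matching zone. The three zone series
#' are compositional (they sum to 1), so a pathway tightly coupled to one
#' zone is necessarily far from the complementary ones; averaging over
#' zones would cancel exactly the signal being ranked. The per-zone columns
#' are retained, and `aggregate = "mean"` is available, so alternative
#' summaries stay computable.
#'
#' @param pathway_profiles named list of numeric profiles, or a
#'   pathways x samples matrix with rownames.
#' @param zone_series 3 x samples matrix with rows Zone1..Zone3 (as from
#'   [zone_proportion_series()]), or a list of three series.
#' @param aggregate `"min"` (default; best-matching zone) or `"mean"`.
#' @return data.frame with columns `pathway`, `dtw_zone1`, `dtw_zone2`,
#'   `dtw_zone3`, `aggregate`, `rank`, sorted by rank.
#' @export
couple_pathways_to_zonation <- function(pathway_profiles, zone_series,
                                        aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(pathway_profiles)) {
    pathway_profiles <- stats::setNames(
      lapply(seq_len(nrow(pathway_profiles)), function(i) pathway_profiles[i, ]),
      rownames(pathway_profiles)
    )
  }
  if (is.matrix(zone_series)) {
    zone_series <- stats::setNames(
      lapply(seq_len(nrow(zone_series)), function(i) zone_series[i, ]),
      rownames(zone_series)
    )
  }
  if (length(zone_series) != 3) stop("three zone series are required")
  lens <- c(lengths(pathway_profiles), lengths(zone_series))
  if (length(unique(lens)) != 1) {
    bad <- names(lens)[lens != stats::median(lens)]
    stop("profiles with mismatched lengths: ", paste(unique(bad), collapse = ", "))
  }
  d <- t(vapply(pathway_profiles, function(p) {
    vapply(zone_series, function(z) dtw_distance(p, z, z_normalize = TRUE),
           numeric(1))
  }, numeric(3)))
  out <- data.frame(
    pathway = names(pathway_profiles),
    dtw_zone1 = d[, 1], dtw_zone2 = d[, 2], dtw_zone3 = d[, 3],
    aggregate = if (aggregate == "min") apply(d, 1, min) else rowMeans(d),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ord <- order(out$aggregate, out$pathway)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
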