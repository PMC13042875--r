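#' Relative specificity score for regulon-group association
#'
#' For each regulon, the RSS contrasts its mean activity in the target cell
#' group with its mean activity over all other cells pooled, normalized by
#' the regulon's maximum activity over all cells:
#' `rss = (target_activity - other_activity) / max_activity`.
#' A regulon whose maximum activity is 0 scores 0 (keeping the table
#' totally ordered). For non-negative activities the score lies in
#' \[-1, 1\]; higher values indicate greater specificity.
#'
#' @param activity regulons x cells numeric matrix of non-negative
#'   activities, with regulon rownames, or a `regulon_activity` object from
#'   [simulate_regulon_activities()].
#' @param group per-cell group labels (taken from the object when
#'   `activity` is a `regulon_activity`).
#' @param target_group the group to score specificity for; must be present
#'   and must not cover all cells.
#' @return data.frame with columns `regulon`, `target_activity`,
#'   `other_activity`, `max_activity`, `rss`, sorted by decreasing `rss`
#'   (ties broken lexicographically).
#' @export
regulon_rss <- function(activity, group = NULL, target_group) {
  if (inherits(activity, "regulon_activity")) {
    if (is.null(group)) group <- activity$group
    activity <- activity$activity
  }
  if (is.null(group)) stop("per-cell group labels are required")
  if (length(group) != ncol(activity)) {
    stop("`group` must have one label per cell")
  }
  in_target <- group == target_group
  if (!any(in_target)) stop("target group has no cells: ", target_group)
  if (all(in_target)) stop("target group covers all cells; no complement")
  target_activity <- rowMeans(activity[, in_target, drop = FALSE])
  other_activity <- rowMeans(activity[, !in_target, drop = FALSE])
  max_activity <- apply(activity, 1, max)
  rss <- ifelse(max_activity == 0, 0,
                (target_activity - other_activity) / max_activity)
  out <- data.frame(
    regulon = rownames(activity),
    target_activity = target_activity,
    other_activity = other_activity,
    max_activity = max_activity,
    rss = rss,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$rss, out$regulon), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Top group-specific regulons
#'
#' @param table an [regulon_rss()] result.
#' @param k number of regulons to return (>= 1); `k` beyond the table size
#'   returns the full sorted list with a warning.
#' @return character vector of regulon names by decreasing RSS (ties
#'   broken lexicographically).
#' @export
top_specific_regulons <- function(table, k) {
  if (k < 1) stop("k must be >= 1")
  ord <- order(-table$rss, table$regulon)
  if (k > nrow(table)) {
    warning("k exceeds the number of regulons; returning all")
    k <- nrow(table)
  }
  table$regulon[ord][seq_len(k)]
}
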