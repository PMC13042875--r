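#' Impute zero iBAQ_IgG values and compute the log2 iBAQ ratio
#'
#' Zeros in `ibaq_igg` are replaced by half the table-wide minimum non-zero
#' `ibaq_igg` (so the ratio is defined), then
#' `log2_ibaq_ratio = log2(ibaq_exp / ibaq_igg_imputed)` is added per
#' protein. Non-zero values are never changed.
#'
#' @param table a [protein_table()].
#' @return the table with columns `ibaq_igg_imputed` and
#'   `log2_ibaq_ratio` added.
#' @export
impute_and_log_ratio <- function(table) {
  stopifnot(inherits(table, "protein_table"))
  nz <- table$ibaq_igg[table$ibaq_igg > 0]
  if (length(nz) == 0) {
    stop("all ibaq_igg values are zero; half-minimum imputation is undefined")
  }
  half_min <- min(nz) / 2
  imput <- ifelse(table$ibaq_igg == 0, half_min, table$ibaq_igg)
  table$ibaq_igg_imputed <- imput
  table$log2_ibaq_ratio <- log2(table$ibaq_exp / imput)
  table
}

.igg_columns <- function(table) {
  grep("^intensity_igg_", names(table), value = TRUE)
}

#' Stepwise high-confidence interactor filter
#'
#' Applies the Co-IP-MS filter cascade, logging one step per rule:
#' \enumerate{
#'   \item QC: keep `unique_peptides >= 2`, then `score >= 30`, then
#'     `coverage_pct >= 5` (each rule its own logged step).
#'   \item Specificity: keep fold change
#'     `FC = intensity_exp / mean(IgG replicates)` strictly above `fc_min`
#'     (a zero IgG mean passes by convention), then keep
#'     `intensity_exp > mu_IgG + sd_mult * sigma_IgG`, where mu and sigma
#'     are taken over the protein's own IgG replicates when at least 2
#'     exist, and over the table-wide IgG intensity distribution otherwise.
#'   \item Contaminants: drop records flagged as contaminant or listed in
#'     `contaminants`.
#'   \item Abundance: `iBAQ\% = 100 * ibaq_exp / sum(ibaq_exp)` over the
#'     post-contaminant table; keep `iBAQ\% >= ibaq_pct_min`.
#' }
#'
#' @param table a [protein_table()] (raw intensities; [impute_and_log_ratio()]
#'   is applied internally if its columns are absent).
#' @param contaminants additional known-contaminant protein ids.
#' @param fc_min strict fold-change threshold (default 4).
#' @param sd_mult IgG standard-deviation multiplier (default 3).
#' @param ibaq_pct_min iBAQ percentage keep-threshold (default 0.1).
#' @return list with `table` (surviving records, plus `fc`, `log2_fc`,
#'   `ibaq_pct`, `log2_ibaq_ratio` columns) and `report` (a `filter_report`
#'   data.frame with columns `step`, `n_in`, `n_out`, `removed`).
#' @export
filter_high_confidence <- function(table, contaminants = character(),
                                   fc_min = 4, sd_mult = 3, ibaq_pct_min = 0.1) {
  stopifnot(inherits(table, "protein_table"))
  if (!"log2_ibaq_ratio" %in% names(table)) {
    table <- impute_and_log_ratio(table)
  }
  igg_cols <- .igg_columns(table)
  igg <- as.matrix(table[igg_cols])
  if (any(igg < 0) || any(table$intensity_exp < 0)) stop("negative intensities")
  igg_mean <- rowMeans(igg)
  table$fc <- ifelse(igg_mean == 0, Inf, table$intensity_exp / igg_mean)
  table$log2_fc <- log2(table$fc)
  pooled_mu <- mean(igg)
  pooled_sd <- stats::sd(as.numeric(igg))
  thr <- if (ncol(igg) >= 2) {
    igg_mean + sd_mult * apply(igg, 1, stats::sd)
  } else {
    rep(pooled_mu + sd_mult * pooled_sd, nrow(table))
  }
  table$igg_intensity_threshold <- thr

  report <- data.frame(step = character(0), n_in = integer(0),
                       n_out = integer(0), removed = character(0),
                       stringsAsFactors = FALSE)
  apply_step <- function(tab, step, keep) {
    removed <- tab$protein_id[!keep]
    report <<- rbind(report, data.frame(
      step = step, n_in = nrow(tab), n_out = sum(keep),
      removed = paste(removed, collapse = ","), stringsAsFactors = FALSE
    ))
    tab[keep, , drop = FALSE]
  }

  t1 <- apply_step(table, "qc_unique_peptides", table$unique_peptides >= 2)
  t2 <- apply_step(t1, "qc_score", t1$score >= 30)
  t3 <- apply_step(t2, "qc_coverage", t2$coverage_pct >= 5)
  t4 <- apply_step(t3, "specificity_fold_change", t3$fc > fc_min)
  t5 <- apply_step(t4, "specificity_intensity",
                   t4$intensity_exp > t4$igg_intensity_threshold)
  contam <- t5$contaminant | t5$protein_id %in% contaminants
  t6 <- apply_step(t5, "contaminants", !contam)
  ibaq_pct <- if (nrow(t6) > 0) 100 * t6$ibaq_exp / sum(t6$ibaq_exp) else numeric(0)
  t6$ibaq_pct <- ibaq_pct
  t7 <- apply_step(t6, "abundance_ibaq_pct", ibaq_pct >= ibaq_pct_min)

  class(report) <- c("filter_report", "data.frame")
  attr(t7, "experiment") <- attr(table, "experiment")
  list(table = t7, report = report)
}

#' Consensus interactors across two pull-down experiments
#'
#' Intersects the survivors of two independently filtered experiments and
#' averages their log2 fold changes and log2 iBAQ ratios. An empty
#' intersection is allowed but warned about.
#'
#' @param ctl,oe `table` elements of two [filter_high_confidence()] results
#'   (must carry `log2_fc` and `log2_ibaq_ratio`).
#' @return data.frame with columns `protein_id`, `mean_log2_fc`,
#'   `mean_log2_ibaq_ratio`, sorted by decreasing `mean_log2_fc`.
#' @export
consensus_interactors <- function(ctl, oe) {
  need <- c("protein_id", "log2_fc", "log2_ibaq_ratio")
  stopifnot(all(need %in% names(ctl)), all(need %in% names(oe)))
  ids <- intersect(ctl$protein_id, oe$protein_id)
  if (length(ids) == 0) {
    warning("no overlapping proteins between the two experiments")
    return(data.frame(protein_id = character(0), mean_log2_fc = numeric(0),
                      mean_log2_ibaq_ratio = numeric(0)))
  }
  i1 <- match(ids, ctl$protein_id)
  i2 <- match(ids, oe$protein_id)
  out <- data.frame(
    protein_id = ids,
    mean_log2_fc = (ctl$log2_fc[i1] + oe$log2_fc[i2]) / 2,
    mean_log2_ibaq_ratio = (ctl$log2_ibaq_ratio[i1] + oe$log2_ibaq_ratio[i2]) / 2,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$mean_log2_fc, out$protein_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
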