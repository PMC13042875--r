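#' @title Synthetic-data generators with planted ground truth
#' @description Every input the pipeline consumes can be generated here:
#' a zonated lobule reference, hepatocyte state groups, a transplantation
#' timecourse, regulon activities and paired Co-IP-MS tables. Each generator
#' returns its planted truth explicitly so downstream recovery is testable
#' without external downloads.
#' @name simulate
NULL

# 18 candidate zonation markers; the first four carry the strong planted
# gradients, the rest weak ones. Layer 1 is pericentral by convention, so
# "pericentral-high" genes decrease from layer 1 to layer 8.
.zonation_candidates <- c(
  "Cyp2f2", "Cyp2e1", "Glul", "Ass1",
  "Alb", "Pck1", "Cyp1a2", "Oat", "Gulo", "Sds", "Hal",
  "Arg1", "Pon1", "Cps1", "G6pc", "Axin2", "Lgr5", "Cyp7a1"
)
.strong_marker_truth <- c(
  Cyp2f2 = "periportal-high", Cyp2e1 = "pericentral-high",
  Glul = "pericentral-high", Ass1 = "periportal-high"
)

#' Candidate zonation marker genes
#'
#' The 18 candidate markers the zonation stages work from; the first four
#' (Cyp2f2, Cyp2e1, Glul, Ass1) are the canonical strong-gradient markers.
#' @return character vector of 18 gene names.
#' @export
zonation_marker_candidates <- function() .zonation_candidates

# Poisson-sample counts from log-scale means plus optional log-normal noise.
.sample_counts <- function(log_mean, noise_sd) {
  lam <- exp(log_mean + if (noise_sd > 0) {
    stats::rnorm(length(log_mean), 0, noise_sd)
  } else 0)
  matrix(
    stats::rpois(length(lam), lam),
    nrow = nrow(log_mean), dimnames = dimnames(log_mean)
  )
}

#' Simulate an 8-layer zonated liver reference
#'
#' Emulates a lobule-layer-annotated hepatocyte reference: 18 candidate
#' zonation markers plus background genes over `n_layers * n_cells_per_layer`
#' cells. Exactly four markers (Cyp2f2, Cyp2e1, Glul, Ass1) carry strictly
#' monotone mean gradients across layers 1..8 with slope scaled by
#' `effect_size` (layer 1 pericentral: Cyp2e1 and Glul decrease, Cyp2f2 and
#' Ass1 increase); the remaining 14 carry weak gradients (at most 20% of
#' `effect_size`); background genes are layer-independent. Log-scale means
#' receive Gaussian noise of sd `noise_sd` and are Poisson-sampled to counts.
#'
#' @param config a [sim_config()]; `n_layers` must be 8.
#' @return a `layered_reference`: list with `expression` (raw-count
#'   [expression_matrix()] whose cell_meta carries a `layer` column),
#'   `layer` (integer vector 1..8), `marker_truth` (the four strong markers
#'   and their gradient direction) and `candidates` (all 18 markers).
#' @export
simulate_zonated_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_layers != 8L) {
    stop("the zonation classifier contract assumes 8 lobule layers")
  }
  with_sim_seed(config, 101L, {
    n_layers <- config$n_layers
    n_per <- config$n_cells_per_layer
    layer <- rep(seq_len(n_layers), each = n_per)
    n_cells <- length(layer)
    bg <- sprintf("Bg%04d", seq_len(config$n_background_genes))
    gene_names <- c(.zonation_candidates, bg)

    # layer coordinate scaled to [-1, 1]; slope in log-mean units
    pos <- (layer - (n_layers + 1) / 2) / ((n_layers - 1) / 2)
    base <- log(5)
    dir4 <- c(Cyp2f2 = 1, Cyp2e1 = -1, Glul = -1, Ass1 = 1)
    weak <- .zonation_candidates[-(1:4)]
    weak_slope <- stats::runif(length(weak), -0.2, 0.2) * config$effect_size
    names(weak_slope) <- weak
    slopes <- c(dir4 * config$effect_size, weak_slope,
                stats::setNames(rep(0, length(bg)), bg))
    # background genes span a realistic range of baseline abundances
    base_per_gene <- c(
      stats::setNames(rep(base, length(.zonation_candidates)), .zonation_candidates),
      stats::setNames(stats::rnorm(length(bg), base, 0.8), bg)
    )

    log_mean <- base_per_gene[gene_names] + outer(slopes[gene_names], pos)
    dimnames(log_mean) <- list(gene_names, sprintf("ref_cell_%05d", seq_len(n_cells)))
    counts <- .sample_counts(log_mean, config$noise_sd)

    meta <- data.frame(
      cell_id = colnames(counts),
      sample = "reference", group = "reference", timepoint = "reference",
      layer = layer, stringsAsFactors = FALSE
    )
    structure(
      list(
        expression = expression_matrix(counts, meta),
        layer = layer,
        marker_truth = .strong_marker_truth,
        candidates = .zonation_candidates
      ),
      class = "layered_reference"
    )
  })
}

#' Simulate hepatocyte state groups with planted signatures
#'
#' Emulates the discrete donor/host hepatocyte states observed after
#' transplantation. Plants: an `Afp` gene whose group means obey
#' Afp_high > Host > Afp_low > Adult (spacing scaled by `effect_size`); a
#' reprogramming signature of `n_ars_genes` genes elevated in the three
#' Afp groups relative to Adult; cell-cycle genes elevated only in
#' Afp_low_cycling; and one co-expression module in which Afp carries the
#' highest factor loading (the planted hub for network tests).
#'
#' @param config a [sim_config()]; `group_sizes` must name Adult, Afp_low,
#'   Afp_low_cycling, Afp_high and Host.
#' @return list with `expression` (raw counts, group labels in cell_meta),
#'   `afp_gene`, `ars_genes`, `cycle_genes`, `module_genes`,
#'   `module_loadings` (named, Afp maximal) and `group_levels`.
#' @export
simulate_state_groups <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  required <- c("Adult", "Afp_low", "Afp_low_cycling", "Afp_high", "Host")
  missing <- setdiff(required, names(config$group_sizes))
  if (length(missing) > 0) {
    stop("`group_sizes` is missing required groups: ", paste(missing, collapse = ", "))
  }
  with_sim_seed(config, 202L, {
    sizes <- config$group_sizes[required]
    group <- rep(required, times = sizes)
    n_cells <- length(group)
    es <- config$effect_size

    ars <- sprintf("Ars%03d", seq_len(config$n_ars_genes))
    cyc <- sprintf("Cyc%03d", seq_len(config$n_cycle_genes))
    mod_extra <- sprintf("Mod%03d", seq_len(config$n_module_genes - 1L))
    module_genes <- c("Afp", mod_extra)
    bg <- sprintf("Bg%04d", seq_len(config$n_background_genes))
    gene_names <- c("Afp", ars, cyc, mod_extra, bg)

    base <- log(5)
    levels <- c(Adult = 0, Afp_low = 1, Afp_low_cycling = 1, Host = 2, Afp_high = 3)
    # latent module factor: group-driven Afp intensity plus per-cell noise
    factor_c <- es * levels[group] + stats::rnorm(n_cells)
    loadings <- stats::setNames(
      c(1, seq(0.9, 0.3, length.out = length(mod_extra))), module_genes
    )

    # planted genes sit at the shared baseline; background genes span a
    # realistic abundance range so expression-matched control bins are
    # dominated by unperturbed genes
    base_per_gene <- stats::setNames(rep(base, length(gene_names)), gene_names)
    base_per_gene[bg] <- stats::rnorm(length(bg), base, 0.8)
    log_mean <- matrix(base_per_gene, nrow = length(gene_names), ncol = n_cells,
                       dimnames = list(gene_names,
                                       sprintf("grp_cell_%05d", seq_len(n_cells))))
    log_mean[module_genes, ] <- base +
      loadings[module_genes] %o% factor_c
    in_afp_groups <- group %in% c("Afp_low", "Afp_low_cycling", "Afp_high")
    log_mean[ars, in_afp_groups] <- log_mean[ars, in_afp_groups] + es
    log_mean[cyc, group == "Afp_low_cycling"] <-
      log_mean[cyc, group == "Afp_low_cycling"] + 1.2 * es

    counts <- .sample_counts(log_mean, config$noise_sd)
    meta <- data.frame(
      cell_id = colnames(counts), sample = "groups", group = group,
      timepoint = "groups", stringsAsFactors = FALSE
    )
    list(
      expression = expression_matrix(counts, meta),
      afp_gene = "Afp",
      ars_genes = ars,
      cycle_genes = cyc,
      module_genes = module_genes,
      module_loadings = loadings,
      group_levels = levels
    )
  })
}

# Fixed zone-proportion drift over the 8 study timepoints: Zone2 rises after
# transplantation, then falls back as zonation is re-established.
.default_zone2 <- c(0.30, 0.45, 0.55, 0.50, 0.42, 0.48, 0.40, 0.34)
.default_zone1 <- c(0.40, 0.30, 0.20, 0.25, 0.30, 0.27, 0.32, 0.36)

#' Simulate a transplantation timecourse
#'
#' Emulates the 8-sample timecourse (R0_0W through R2_12W): per-sample cell
#' populations whose lobule-layer composition follows smoothly drifting
#' Zone1-3 proportions (Zone2 rises then falls), plus pathway gene
#' signatures whose per-sample activity follows planted profiles. One
#' pathway ("Jak_Stat") is coupled: its true profile is an affine transform
#' of the Zone2 proportion series plus `noise_sd` Gaussian noise; decoy
#' profiles are independent standard-normal draws. Each sample's expression
#' embeds the zonation marker gradients (so layers are predictable) and
#' shifts each pathway signature by its z-scored profile value.
#'
#' @param config a [sim_config()] with at least 3 timepoints.
#' @return a `timecourse_sim`: list with `samples` (named list of raw-count
#'   [expression_matrix()]), `true_zone_proportions` (3 x n_samples matrix,
#'   rows Zone1..Zone3, columns summing to 1), `true_pathway_profiles`
#'   (pathways x samples matrix), `planted_coupled_pathway`,
#'   `pathway_signatures` (named list of gene sets) and `marker_truth`.
#' @export
simulate_timecourse <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tps <- config$timepoints
  n_t <- length(tps)
  with_sim_seed(config, 303L, {
    if (n_t == 8L) {
      z2 <- .default_zone2
      z1 <- .default_zone1
    } else {
      # smooth rise-then-fall for non-default lengths
      u <- seq(0, 1, length.out = n_t)
      z2 <- 0.3 + 0.25 * sin(pi * u)
      z1 <- 0.4 - 0.2 * sin(pi * u)
    }
    z3 <- 1 - z1 - z2
    props <- rbind(Zone1 = z1, Zone2 = z2, Zone3 = z3)
    colnames(props) <- tps

    planted <- "Jak_Stat"
    decoys <- sprintf("Pathway%02d", seq_len(config$n_decoy_pathways))
    pathways <- c(planted, decoys)
    profiles <- matrix(0, nrow = length(pathways), ncol = n_t,
                       dimnames = list(pathways, tps))
    profiles[planted, ] <- 0.5 + 8 * z2 +
      stats::rnorm(n_t, 0, config$noise_sd)
    profiles[decoys, ] <- stats::rnorm(length(decoys) * n_t)

    n_pg <- config$n_pathway_genes
    pathway_signatures <- stats::setNames(lapply(seq_along(pathways), function(i) {
      sprintf("%s_g%02d", pathways[i], seq_len(n_pg))
    }), pathways)

    zone_layers <- list(Zone1 = 7:8, Zone2 = 4:6, Zone3 = 1:3)
    bg <- sprintf("Bg%04d", seq_len(config$n_background_genes))
    gene_names <- c(.zonation_candidates, unlist(pathway_signatures, use.names = FALSE), bg)
    base <- log(5)
    dir4 <- c(Cyp2f2 = 1, Cyp2e1 = -1, Glul = -1, Ass1 = 1)
    weak <- .zonation_candidates[-(1:4)]
    weak_slope <- stats::setNames(
      stats::runif(length(weak), -0.2, 0.2) * config$effect_size, weak
    )
    marker_slopes <- c(dir4 * config$effect_size, weak_slope)
    # per-gene baselines shared across samples; background spans a
    # realistic abundance range
    base_per_gene <- stats::setNames(rep(base, length(gene_names)), gene_names)
    base_per_gene[bg] <- stats::rnorm(length(bg), base, 0.8)

    prof_z <- t(apply(profiles, 1, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }))

    n_cells <- config$n_cells_per_sample
    samples <- stats::setNames(vector("list", n_t), tps)
    for (t_i in seq_len(n_t)) {
      # largest-remainder apportionment of cells to zones
      raw <- props[, t_i] * n_cells
      n_zone <- floor(raw)
      rem <- n_cells - sum(n_zone)
      if (rem > 0) {
        add <- order(raw - n_zone, decreasing = TRUE)[seq_len(rem)]
        n_zone[add] <- n_zone[add] + 1
      }
      layer <- unlist(lapply(names(zone_layers), function(z) {
        sample(zone_layers[[z]], n_zone[[z]], replace = TRUE)
      }), use.names = FALSE)
      pos <- (layer - 4.5) / 3.5

      log_mean <- matrix(base_per_gene, nrow = length(gene_names), ncol = n_cells,
                         dimnames = list(gene_names, sprintf(
                           "%s_cell_%04d", tps[t_i], seq_len(n_cells)
                         )))
      log_mean[names(marker_slopes), ] <- base + marker_slopes %o% pos
      for (p in pathways) {
        log_mean[pathway_signatures[[p]], ] <-
          log_mean[pathway_signatures[[p]], ] + 0.4 * prof_z[p, t_i]
      }
      counts <- .sample_counts(log_mean, config$noise_sd)
      meta <- data.frame(
        cell_id = colnames(counts), sample = tps[t_i], group = "timecourse",
        timepoint = tps[t_i], layer = layer, stringsAsFactors = FALSE
      )
      samples[[t_i]] <- expression_matrix(counts, meta)
    }

    stopifnot(all(abs(colSums(props) - 1) < 1e-9))
    structure(
      list(
        samples = samples,
        true_zone_proportions = props,
        true_pathway_profiles = profiles,
        planted_coupled_pathway = planted,
        pathway_signatures = pathway_signatures,
        marker_truth = .strong_marker_truth
      ),
      class = "timecourse_sim"
    )
  })
}

#' Simulate regulon activities with planted group-specific regulons
#'
#' AUC-style non-negative activities (Gamma-distributed) for `n_regulons`
#' regulons over cells drawn from `group_sizes`. One regulon per group is
#' planted as specific: its target-group mean exceeds the other-group mean
#' by `effect_size` times the baseline. The rest are exchangeable decoys.
#'
#' @param config a [sim_config()] with at least 2 groups and 2 regulons.
#' @return a `regulon_activity`: list with `activity` (regulons x cells
#'   matrix), `group` (per-cell labels) and `planted_specific` (named list
#'   group -> planted regulon).
#' @export
simulate_regulon_activities <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  groups <- names(config$group_sizes)
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (config$n_regulons < 2) stop("at least 2 regulons are required")
  with_sim_seed(config, 404L, {
    group <- rep(groups, times = config$group_sizes)
    n_cells <- length(group)
    regs <- sprintf("Reg%03d", seq_len(config$n_regulons))
    base_scale <- 0.05
    act <- matrix(
      stats::rgamma(config$n_regulons * n_cells, shape = 2, scale = base_scale),
      nrow = config$n_regulons,
      dimnames = list(regs, sprintf("reg_cell_%05d", seq_len(n_cells)))
    )
    planted <- stats::setNames(
      as.list(regs[seq_along(groups)]), groups
    )
    for (g in groups) {
      r <- planted[[g]]
      idx <- group == g
      act[r, idx] <- stats::rgamma(
        sum(idx), shape = 2, scale = base_scale * (1 + config$effect_size)
      )
    }
    structure(
      list(activity = act, group = group, planted_specific = planted),
      class = "regulon_activity"
    )
  })
}

#' Construct a Co-IP-MS protein table
#'
#' @param records data.frame with columns `protein_id`, `unique_peptides`,
#'   `score`, `coverage_pct`, `intensity_exp`, `intensity_igg_1` ..
#'   `intensity_igg_k`, `ibaq_exp`, `ibaq_igg`, `contaminant`.
#' @param experiment experiment label (e.g. "Ctl" or "AFP-OE").
#' @param planted_true optional protein ids planted to survive all filters.
#' @return data.frame of class `protein_table` with `experiment` and
#'   `planted_true` attributes.
#' @export
protein_table <- function(records, experiment, planted_true = NULL) {
  needed <- c("protein_id", "unique_peptides", "score", "coverage_pct",
              "intensity_exp", "ibaq_exp", "ibaq_igg", "contaminant")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("protein table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!any(grepl("^intensity_igg_", names(records)))) {
    stop("protein table needs at least one intensity_igg_<i> column")
  }
  if (anyDuplicated(records$protein_id)) stop("protein_id values must be unique")
  num <- records[setdiff(names(records), c("protein_id", "contaminant"))]
  if (any(!vapply(num, is.numeric, logical(1)))) stop("quantitative columns must be numeric")
  if (any(vapply(num, function(x) any(!is.finite(x) | x < 0), logical(1)))) {
    stop("all quantitative fields must be finite and non-negative")
  }
  structure(records, class = c("protein_table", "data.frame"),
            experiment = experiment, planted_true = planted_true)
}

# Deterministic 12-record table: 4 planted true interactors, 7 near-misses
# each violating exactly one filter rule, and 1 record exclusive to this
# experiment (passes everything but is absent from the partner table).
.coip_records <- function(exclusive_id, jitter) {
  passing <- function(id, ibaq_exp, ibaq_igg, j) {
    data.frame(
      protein_id = id, unique_peptides = 10L + as.integer(round(4 * j)),
      score = 95 + 3 * j,
      coverage_pct = 40 + 2 * j,
      intensity_exp = 1e6 * (1 + 0.05 * j),
      intensity_igg_1 = 1.0e4, intensity_igg_2 = 1.2e4, intensity_igg_3 = 0.8e4,
      ibaq_exp = ibaq_exp, ibaq_igg = ibaq_igg, contaminant = FALSE,
      stringsAsFactors = FALSE
    )
  }
  truths <- do.call(rbind, list(
    passing("P_true1", 3000, 1.0, jitter[1]),
    passing("P_true2", 3000, 0.0, jitter[2]),   # zero iBAQ_IgG: imputation case
    passing("P_true3", 2000, 2.0, jitter[3]),
    passing("P_true4", 2000, 1.5, jitter[4])
  ))
  near <- function(id, ...) {
    r <- passing(id, 500, 1.0, 0)
    dots <- list(...)
    r[names(dots)] <- dots
    r
  }
  misses <- do.call(rbind, list(
    near("NM_peptides", unique_peptides = 1),
    near("NM_score", score = 29),
    near("NM_coverage", coverage_pct = 4.9),
    # FC 3.9 with tight IgG replicates so only the fold-change rule fails
    near("NM_fc", intensity_exp = 3.9e4,
         intensity_igg_1 = 1e4, intensity_igg_2 = 1e4, intensity_igg_3 = 1e4),
    # FC > 4 but experimental intensity below mean IgG + 3*SD
    near("NM_intensity", intensity_exp = 1.7e4,
         intensity_igg_1 = 100, intensity_igg_2 = 10000, intensity_igg_3 = 200),
    near("NM_contaminant", contaminant = TRUE),
    # survives to the abundance step, then iBAQ% < 0.1
    near("NM_ibaq", ibaq_exp = 9)
  ))
  exclusive <- passing(exclusive_id, 1000, 1.2, 0)
  rbind(truths, misses, exclusive)
}

#' Simulate paired Co-IP-MS protein tables
#'
#' Two 12-record tables (experiments "Ctl" and "AFP-OE") with: four planted
#' true interactors that pass every filter in both tables (one of them with
#' a zero iBAQ_IgG value to exercise half-minimum imputation); seven
#' near-misses each violating exactly one rule (1 peptide; score 29;
#' coverage 4.9%; fold change 3.9; intensity below mean IgG + 3*SD;
#' contaminant flag; iBAQ% below 0.1); and one record present in only one
#' experiment. The consensus of the filtered pair equals `planted_true`.
#'
#' @param config a [sim_config()] (only `seed` is used, for field jitter on
#'   records far from any decision boundary).
#' @return list with `ctl` and `oe` ([protein_table()] objects) and
#'   `planted_true` (character vector of 4 protein ids).
#' @export
simulate_coip_tables <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 505L, {
    planted <- c("P_true1", "P_true2", "P_true3", "P_true4")
    ctl <- protein_table(.coip_records("P_ctl_only", stats::runif(4)),
                         "Ctl", planted)
    oe <- protein_table(.coip_records("P_oe_only", stats::runif(4)),
                        "AFP-OE", planted)
    list(ctl = ctl, oe = oe, planted_true = planted)
  })
}
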