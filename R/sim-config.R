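#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults define
#' the study conditions the generators emulate: an 8-layer zonated lobule
#' reference, five hepatocyte state groups (Adult, Afp_low, Afp_low_cycling,
#' Afp_high, Host), an 8-sample transplantation timecourse, regulon
#' activities with planted group-specific regulons, and paired Co-IP-MS
#' tables. A fixed `seed` makes every generator byte-reproducible.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param n_cells_per_layer cells per lobule layer in the zonated reference.
#' @param n_layers number of lobule layers; the classifier contract fixes 8.
#' @param noise_sd non-negative per-gene Gaussian noise sd on the log scale.
#' @param n_background_genes layer/group-independent filler genes.
#' @param group_sizes named integer vector of cells per hepatocyte state
#'   group; must include Adult, Afp_low, Afp_low_cycling, Afp_high, Host
#'   for [simulate_state_groups()].
#' @param timepoints ordered sample names of the transplantation timecourse.
#' @param effect_size positive planted signal magnitude (log-scale shift for
#'   expression, relative activity lift for regulons).
#' @param n_ars_genes size of the planted reprogramming signature.
#' @param n_cycle_genes number of planted cell-cycle genes.
#' @param n_module_genes size of the planted co-expression module (anchored
#'   on Afp as its strongest-loading hub).
#' @param n_regulons regulons in the simulated activity matrix.
#' @param n_decoy_pathways uncoupled pathway profiles in the timecourse.
#' @param n_cells_per_sample cells per timecourse sample.
#' @param n_pathway_genes genes per simulated pathway signature.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_layer = 150L,
                       n_layers = 8L,
                       noise_sd = 0.3,
                       n_background_genes = 2000L,
                       group_sizes = c(
                         Adult = 300L, Afp_low = 250L, Afp_low_cycling = 50L,
                         Afp_high = 250L, Host = 250L
                       ),
                       timepoints = c(
                         "R0_0W", "R1_1W", "R1_3W", "R1_6W",
                         "R1_12W", "R2_3W", "R2_6W", "R2_12W"
                       ),
                       effect_size = 2,
                       n_ars_genes = 78L,
                       n_cycle_genes = 20L,
                       n_module_genes = 30L,
                       n_regulons = 20L,
                       n_decoy_pathways = 20L,
                       n_cells_per_sample = 500L,
                       n_pathway_genes = 15L) {
  cfg <- list(
    seed = as.integer(seed),
    n_cells_per_layer = as.integer(n_cells_per_layer),
    n_layers = as.integer(n_layers),
    noise_sd = noise_sd,
    n_background_genes = as.integer(n_background_genes),
    group_sizes = group_sizes,
    timepoints = as.character(timepoints),
    effect_size = effect_size,
    n_ars_genes = as.integer(n_ars_genes),
    n_cycle_genes = as.integer(n_cycle_genes),
    n_module_genes = as.integer(n_module_genes),
    n_regulons = as.integer(n_regulons),
    n_decoy_pathways = as.integer(n_decoy_pathways),
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_pathway_genes = as.integer(n_pathway_genes)
  )
  sizes <- c(
    cfg$n_cells_per_layer, cfg$n_layers, cfg$n_background_genes,
    cfg$group_sizes, cfg$n_ars_genes, cfg$n_cycle_genes, cfg$n_module_genes,
    cfg$n_regulons, cfg$n_cells_per_sample, cfg$n_pathway_genes
  )
  if (any(sizes < 1)) stop("all sizes in a sim_config must be >= 1")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (cfg$effect_size < 0) stop("`effect_size` must be non-negative")
  if (is.null(names(cfg$group_sizes)) || any(names(cfg$group_sizes) == "")) {
    stop("`group_sizes` must be a named vector")
  }
  if (length(cfg$timepoints) < 3) stop("at least 3 timepoints are required")
  class(cfg) <- "sim_config"
  cfg
}

# Run `code` under a seed derived from the config seed and a per-generator
# offset, so each generator is reproducible yet draws distinct streams.
with_sim_seed <- function(config, offset, code) {
  withr::with_seed(config$seed + offset, code)
}
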