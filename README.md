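# hepregen

Analysis toolkit for single-cell studies of hepatocyte transplantation and
liver regeneration. After mature hepatocytes are transplanted into an
injured liver, the donor cells transiently reprogram into an
alpha-fetoprotein-positive (Afp⁺) state, re-proliferate, and then
re-acquire the spatial identity ("zonation") of the hepatic lobule.
`hepregen` implements the quantitative machinery needed to characterize
that process from single-cell expression data, plus a seeded synthetic-data
generator so the entire pipeline is testable without any external dataset.

## What it computes

* **Module scores with binned controls** — per-cell gene-set activity
  `score(c) = mean(sig genes) − mean(expression-matched controls)`, with
  controls drawn from 24 equal-frequency average-expression bins (100 per
  signature gene). Cycling cells are called at
  `score > mean + 3·sd` (sample sd).
* **ARS construction** — the Afp⁺ reprogrammed-hepatocyte signature as the
  union of Wilcoxon rank-sum DEGs (`log2FC > 1`, BH `adj_p < 0.05`) and
  temporally upregulated genes from fuzzy c-means clustering of z-scored
  timecourse profiles.
* **Zonation** — a NIPALS PLSR coordinate on 18 z-scored zonation markers
  (layer 1 pericentral), attribution-based selection of the top-4 markers
  (Cyp2f2, Cyp2e1, Glul, Ass1), a class-weighted gradient-boosted 8-layer
  classifier with stratified 5-fold CV (macro one-vs-rest AUC), and the
  fixed grouping L1–L3 → Zone3, L4–L6 → Zone2, L7–L8 → Zone1.
* **DTW coupling** — dynamic time warping
  `D(i,j) = |a_i − b_j| + min(D(i−1,j), D(i,j−1), D(i−1,j−1))` between
  z-normalized pathway-activity and zone-proportion series; pathways ranked
  by their distance to the best-matching zone.
* **Regulon specificity** —
  `RSS = (target_activity − other_activity) / max_activity` with the
  pooled-complement mean, sorted descending.
* **Co-expression sub-networks** — unsigned `|cor|^β` adjacency (β = 6),
  topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j)+1−a_ij)`,
  module eigengene (first PC) and kME, and anchor-centric extraction
  (`kME > 0.25`, TOM to anchor `> 0.025`).
* **Co-IP-MS interactor filtering** — stepwise: ≥2 unique peptides,
  score ≥ 30, coverage ≥ 5%, fold change > 4 over mean IgG, intensity >
  mean IgG + 3·sd, contaminant removal, iBAQ% ≥ 0.1; half-minimum
  imputation of zero iBAQ_IgG; consensus = intersection of two experiments
  with averaged log2 ratios.

## Worked example

Simulate the five hepatocyte state groups with planted truth, score the
planted signature, call cycling cells, and run differential expression:

```r
library(hepregen)

cfg  <- sim_config(seed = 1)
sim  <- simulate_state_groups(cfg)
expr <- normalize_expression(sim$expression)

scores <- module_score(expr, gene_signature("ARS", sim$ars_genes), seed = 1)
round(tapply(scores, expr$cell_meta$group, mean), 3)
#>           Adult        Afp_high         Afp_low Afp_low_cycling            Host
#>          -0.481           0.466           0.513           0.516          -0.483

cyc <- classify_cycling(module_score(expr, gene_signature("cycle", sim$cycle_genes), seed = 1))
table(group = expr$cell_meta$group, cycling = as.logical(cyc))
#>                  cycling
#> group             FALSE TRUE
#>   Adult             300    0
#>   Afp_high          250    0
#>   Afp_low           250    0
#>   Afp_low_cycling     0   50
#>   Host              250    0

meta <- expr$cell_meta
de <- rank_sum_de(expr, meta$cell_id[meta$group == "Afp_high"],
                  meta$cell_id[meta$group == "Adult"])
head(de, 3)
#>       gene  log2_fc      p_value        adj_p pct_a     pct_b
#> 1      Afp 6.876736 8.278392e-91 1.178129e-88     1 0.9266667
#> 103 Mod004 5.477701 8.336712e-91 1.178129e-88     1 0.9433333
#> 102 Mod003 5.688054 8.345023e-91 1.178129e-88     1 0.9466667
```

The module scores separate the three Afp⁺ reprogrammed states (≈ +0.5)
from Adult and Host hepatocytes (≈ −0.5); the cycling caller flags exactly
the planted cycling subpopulation; and the strongest DEGs are the planted
Afp gene and its co-expression module partners.

The full chain — simulate a timecourse, score pathways, predict zones,
rank pathways by DTW coupling — is one call:

```r
rep <- run_timecourse_pipeline(sim_config(seed = 42), out = "report.json")
head(rep$coupling, 3)   # planted "Jak_Stat" pathway at rank 1 for this seed
rep$cv_auc              # zonation classifier CV macro AUC, ~0.96
```

A thin command-line wrapper over the same functions ships in
`inst/cli/hepregen` (subcommands `simulate`, `dtw-rank`, `rss`,
`coip-filter`, `pipeline`).

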