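small_cfg <- function(...) {
  sim_config(
    n_cells_per_layer = 40L, n_background_genes = 300L,
    group_sizes = c(Adult = 60L, Afp_low = 50L, Afp_low_cycling = 15L,
                    Afp_high = 50L, Host = 50L),
    n_cells_per_sample = 60L, ...
  )
}

test_that("sim_config validates sizes, noise and groups", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(n_cells_per_layer = 0), ">= 1")
  expect_error(sim_config(group_sizes = c(10, 10)), "named")
  expect_error(sim_config(timepoints = c("a", "b")), "3 timepoints")
})

test_that("zonated reference plants the four strong monotone markers", {
  ref <- simulate_zonated_reference(small_cfg(seed = 1L, noise_sd = 0))
  expect_setequal(names(ref$marker_truth), c("Cyp2f2", "Cyp2e1", "Glul", "Ass1"))
  v <- ref$expression$values
  for (g in c("Glul", "Cyp2e1")) {
    m <- tapply(as.numeric(v[g, ]), ref$layer, mean)
    expect_true(all(diff(m) < 0), info = g)
  }
  for (g in c("Cyp2f2", "Ass1")) {
    m <- tapply(as.numeric(v[g, ]), ref$layer, mean)
    expect_true(all(diff(m) > 0), info = g)
  }
  expect_setequal(unique(ref$layer), 1:8)
  expect_error(
    simulate_zonated_reference(sim_config(n_layers = 4)),
    "8 lobule layers"
  )
})

test_that("state groups plant the Afp gradient, signatures and cycling genes", {
  g <- simulate_state_groups(small_cfg(seed = 2L))
  expect_length(g$ars_genes, sim_config()$n_ars_genes)
  grp <- g$expression$cell_meta$group
  afp <- as.numeric(g$expression$values[g$afp_gene, ])
  m <- tapply(afp, grp, mean)
  expect_gt(m[["Afp_high"]], m[["Host"]])
  expect_gt(m[["Host"]], m[["Afp_low"]])
  expect_gt(m[["Afp_low"]], m[["Adult"]])
  ars <- Matrix::colMeans(g$expression$values[g$ars_genes, , drop = FALSE])
  by_grp <- tapply(ars, grp, mean)
  expect_gt(by_grp[["Afp_high"]], by_grp[["Adult"]])
  expect_gt(by_grp[["Afp_low"]], by_grp[["Adult"]])
  cyc <- Matrix::colMeans(g$expression$values[g$cycle_genes, , drop = FALSE])
  cyc_grp <- tapply(cyc, grp, mean)
  expect_gt(cyc_grp[["Afp_low_cycling"]], 1.5 * max(cyc_grp[names(cyc_grp) != "Afp_low_cycling"]))
  expect_identical(g$module_genes[which.max(g$module_loadings)], "Afp")
  expect_error(
    simulate_state_groups(sim_config(group_sizes = c(Adult = 10, Host = 10))),
    "missing required groups"
  )
})

test_that("timecourse plants coupled pathway and valid zone proportions", {
  tc <- simulate_timecourse(small_cfg(seed = 3L))
  expect_identical(
    names(tc$samples),
    c("R0_0W", "R1_1W", "R1_3W", "R1_6W", "R1_12W", "R2_3W", "R2_6W", "R2_12W")
  )
  expect_equal(colSums(tc$true_zone_proportions), rep(1, 8),
               ignore_attr = TRUE, tolerance = 1e-9)
  # noiseless planted profile is an affine image of the Zone2 series:
  # identical after z-normalization, so DTW distance is exactly 0
  tc0 <- simulate_timecourse(small_cfg(seed = 3L, noise_sd = 0))
  expect_equal(
    dtw_distance(tc0$true_pathway_profiles[tc0$planted_coupled_pathway, ],
                 tc0$true_zone_proportions["Zone2", ]),
    0
  )
  # different seed: different decoys, same planted coupling structure
  tc2 <- simulate_timecourse(small_cfg(seed = 4L))
  expect_false(identical(tc$true_pathway_profiles["Pathway01", ],
                         tc2$true_pathway_profiles["Pathway01", ]))
  expect_identical(tc2$planted_coupled_pathway, tc$planted_coupled_pathway)
})

test_that("regulon activities are non-negative with planted specificity", {
  ra <- simulate_regulon_activities(small_cfg(seed = 5L, effect_size = 2))
  expect_true(all(ra$activity >= 0))
  expect_length(ra$group, ncol(ra$activity))
  for (grp in names(ra$planted_specific)) {
    r <- ra$planted_specific[[grp]]
    expect_gt(
      mean(ra$activity[r, ra$group == grp]),
      mean(ra$activity[r, ra$group != grp])
    )
  }
})

test_that("every generator is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 11L)
  expect_identical(simulate_zonated_reference(cfg), simulate_zonated_reference(cfg))
  expect_identical(simulate_state_groups(cfg), simulate_state_groups(cfg))
  expect_identical(simulate_timecourse(cfg), simulate_timecourse(cfg))
  expect_identical(simulate_regulon_activities(cfg), simulate_regulon_activities(cfg))
  expect_identical(simulate_coip_tables(cfg), simulate_coip_tables(cfg))
})

test_that("coip tables carry planted truth, one near-miss per rule and an imputation case", {
  cp <- simulate_coip_tables(small_cfg(seed = 6L))
  expect_length(cp$planted_true, 4)
  expect_identical(nrow(cp$ctl), 12L)
  expect_identical(nrow(cp$oe), 12L)
  expect_true(any(cp$ctl$ibaq_igg == 0))
  expect_true(all(cp$planted_true %in% cp$ctl$protein_id))
  expect_true(all(cp$planted_true %in% cp$oe$protein_id))
  # exclusive records differ between experiments
  expect_false("P_oe_only" %in% cp$ctl$protein_id)
  expect_false("P_ctl_only" %in% cp$oe$protein_id)
})
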