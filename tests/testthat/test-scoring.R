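test_that("normalization scales cells to 10k, log-transforms, and guards misuse", {
  v <- matrix(c(9999, 1, 5, 5), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  em <- expression_matrix(v)
  norm <- normalize_expression(em)
  # 9999 of a 10,000-count cell -> log(1 + 9999 * 1e4 / 1e4) = log(10000)
  expect_equal(norm$values["g1", "c1"], log(10000))
  expect_true(norm$normalized)
  expect_error(normalize_expression(norm), "already log-normalized")
  v0 <- v; v0[, 2] <- 0
  expect_error(normalize_expression(expression_matrix(v0)), "c2")
})

test_that("module score is zero on constant data and recovers a planted offset", {
  v <- matrix(2, 60, 30, dimnames = list(sprintf("g%03d", 1:60), sprintf("c%03d", 1:30)))
  em <- norm_em(v)
  sig <- gene_signature("s", rownames(v)[1:5])
  expect_equal(unname(module_score(em, sig, seed = 1)), rep(0, 30))

  # planted offset: signature genes spiked by +delta in half the cells;
  # background genes span a range of baselines so the signature's
  # expression bins are dominated by unperturbed control genes
  set.seed(9)
  delta <- 1
  n_cells <- 1000
  base_means <- rnorm(1000, 3, 0.8)
  v2 <- matrix(rnorm(1000 * n_cells, base_means, 0.1), 1000, n_cells,
               dimnames = list(sprintf("g%04d", 1:1000), sprintf("c%04d", 1:n_cells)))
  v2[1:10, 1:(n_cells / 2)] <- v2[1:10, 1:(n_cells / 2)] + delta
  v2 <- pmax(v2, 0)
  em2 <- norm_em(v2)
  sc <- module_score(em2, gene_signature("s", rownames(v2)[1:10]), seed = 2)
  gap <- mean(sc[1:(n_cells / 2)]) - mean(sc[(n_cells / 2 + 1):n_cells])
  expect_lt(abs(gap - delta), 0.05)

  # seeded determinism, and absent genes dropped with a warning
  expect_identical(module_score(em2, gene_signature("s", rownames(v2)[1:10]), seed = 2), sc)
  expect_warning(
    module_score(em2, gene_signature("s", c(rownames(v2)[1:3], "nope")), seed = 1),
    "dropped"
  )
  expect_error(module_score(em2, gene_signature("s", "nope"), seed = 1), "no signature gene")
})

test_that("random-signature module scores center on zero for exchangeable data", {
  set.seed(21)
  v <- matrix(rnorm(400 * 200, 1.5, 0.3), 400, 200,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("c%03d", 1:200)))
  em <- norm_em(pmax(v, 0))
  means <- vapply(1:20, function(i) {
    sig <- gene_signature("r", sample(rownames(v), 15))
    mean(module_score(em, sig, seed = i))
  }, numeric(1))
  # Monte-Carlo band: mean of 20 random-signature score means around 0
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 0.01)
})

test_that("cycling threshold is mean + 3 sample-sd with strict exceedance", {
  expect_equal(sum(classify_cycling(rep(5, 100))), 0)
  scores <- c(rep(0, 999), 100)
  flags <- classify_cycling(scores)
  expect_identical(which(flags), 1000L)
  # independent closed form for the threshold
  expect_equal(attr(flags, "threshold"), mean(scores) + 3 * sd(scores))
  # affine invariance: a * score + b, a > 0 preserves the flags
  set.seed(4)
  s <- rnorm(500)
  expect_identical(
    as.logical(classify_cycling(s)),
    as.logical(classify_cycling(3.7 * s + 11))
  )
  expect_error(classify_cycling(1), "at least 2")
})

test_that("rank-sum DE matches exact enumeration, symmetry and BH contract", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("g1", paste0("c", 1:6)))
  em <- norm_em(v)
  de <- rank_sum_de(em, paste0("c", 1:3), paste0("c", 4:6))
  # all C(6,3) = 20 rank assignments: two-sided exact p = 2 * 1/20
  expect_equal(de$p_value, 0.1)

  set.seed(2)
  v2 <- matrix(rexp(50 * 12), 50, 12)
  em2 <- norm_em(cbind(v2, v2))
  ids <- colnames(em2$values)
  de2 <- rank_sum_de(em2, ids[1:12], ids[13:24])
  expect_equal(de2$log2_fc, rep(0, 50))
  expect_equal(de2$p_value, rep(1, 50))
  # BH is a monotone step-up transform of the raw p-values
  ord <- order(de2$p_value)
  expect_true(all(de2$adj_p >= de2$p_value - 1e-12))
  expect_true(all(diff(de2$adj_p[ord]) >= -1e-12))
  expect_error(rank_sum_de(em2, ids[1:5], ids[5:10]), "disjoint")
  expect_error(rank_sum_de(em2, ids[1], ids[2:5]), "at least 2")
})

test_that("temporal clustering finds early-peaking genes and drops flat profiles", {
  tps <- c("R0_0W", "R1_1W", "R1_3W", "R1_6W", "R1_12W", "R2_3W", "R2_6W", "R2_12W")
  early <- c(0, 3, 3, 2, 0.5, 1, 0.5, 0)
  late <- c(0, 0.2, 0.5, 1, 3, 2, 2.5, 3)
  profiles <- rbind(
    matrix(rep(early, each = 15), 15, 8),
    matrix(rep(late, each = 15), 15, 8)
  )
  dimnames(profiles) <- list(sprintf("g%02d", 1:30), tps)
  sig <- temporal_up_genes(profiles, k = 2, seed = 1)
  expect_setequal(sig$genes, sprintf("g%02d", 1:15))
  expect_true(all(apply(attr(sig, "membership"), 1, max) > 0.9))
  # seeded stability: clearly separated shapes yield the same gene set
  sig2 <- temporal_up_genes(profiles, k = 2, seed = 99)
  expect_setequal(sig2$genes, sig$genes)

  # flat data: constant profiles are dropped; nothing can satisfy the rule
  flat <- matrix(1, 5, 8, dimnames = list(paste0("f", 1:5), tps))
  expect_warning(s0 <- temporal_up_genes(flat, k = 1, seed = 1), "constant")
  expect_length(s0$genes, 0)
})

test_that("fuzzy c-means agrees with an independent implementation on separated data", {
  set.seed(5)
  tps <- c("R0_0W", "R1_1W", "R1_3W", "R1_6W", "R1_12W", "R2_3W", "R2_6W", "R2_12W")
  Z <- rbind(
    matrix(rnorm(40 * 8, 0, 0.2), 40, 8) + rep(c(2, 2, 1, 0, -1, -1, -2, -1), each = 40),
    matrix(rnorm(40 * 8, 0, 0.2), 40, 8) + rep(c(-2, -1, 0, 1, 2, 2, 1, 0), each = 40)
  )
  dimnames(Z) <- list(paste0("gene", 1:80), tps)
  mine <- hepregen:::.fuzzy_cmeans(Z, k = 2, seed = 1)
  other <- e1071::cmeans(Z, centers = 2, m = 2)
  tab <- table(max.col(mine$membership), other$cluster)
  expect_equal(max(sum(diag(tab)), tab[1, 2] + tab[2, 1]), 80)
})

test_that("signature derivation takes the strict-threshold union and is monotone", {
  de <- data.frame(
    gene = sprintf("d%03d", 1:100),
    log2_fc = c(rep(2, 50), rep(0.2, 50)),
    p_value = rep(1e-4, 100),
    adj_p = c(rep(1e-3, 50), rep(0.2, 50))
  )
  temporal <- gene_signature("t", c(sprintf("d%03d", 39:50), sprintf("t%03d", 1:28)))
  ars <- derive_ars(de, temporal)
  # |DEG| = 50, |temporal| = 40, overlap 12 -> union of 78
  expect_length(ars$genes, 78)
  # boundary: log2_fc exactly at the threshold is excluded (strict >)
  de_b <- de; de_b$log2_fc[1] <- 1.0
  expect_length(derive_ars(de_b, temporal)$genes, 77)
  # monotone: relaxing either threshold never shrinks the signature
  expect_true(all(ars$genes %in% derive_ars(de, temporal, lfc_min = 0.1)$genes))
  expect_true(all(ars$genes %in% derive_ars(de, temporal, alpha = 0.5)$genes))
  empty_t <- structure(list(name = "t", genes = character(0)), class = "gene_signature")
  expect_setequal(derive_ars(de, empty_t)$genes, sprintf("d%03d", 1:50))
})
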