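mk_meta <- function(tissues = "leaf", conditions = "ww", reps = 3) {
  g <- expand.grid(replicate = seq_len(reps), condition = conditions,
                   tissue = tissues, stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s.%s.r%d", g$tissue, g$condition, g$replicate)
  g[, c("sample_id", "tissue", "condition", "replicate")]
}

mk_expr <- function(genes, meta, values) {
  m <- matrix(values, nrow = length(genes), ncol = nrow(meta), byrow = FALSE,
              dimnames = list(genes, meta$sample_id))
  m
}

test_that("the low-expression filter removes only pairs failing in BOTH genes", {
  meta <- mk_meta()
  pairs <- data.frame(bhd_gene = c("d1", "d2", "d3"),
                      bhs_gene = c("s1", "s2", "s3"))
  expr <- rbind(mk_expr(c("d1", "s1"), meta, 0.2),            # both low
                mk_expr("d2", meta, 0.2),                      # d low
                mk_expr("s2", meta, c(5, 0.1, 0.1)),           # s has one hit
                mk_expr(c("d3", "s3"), meta, 8))               # both high
  out <- filter_low_expression(pairs, expr)
  expect_equal(out$filtered, c(TRUE, FALSE, FALSE))
  # threshold 0 keeps everything that is not all-zero
  out0 <- filter_low_expression(pairs, expr, threshold = 0)
  expect_equal(out0$filtered, c(FALSE, FALSE, FALSE))
  # "either" rule also drops the silenced-homeolog pair
  oute <- filter_low_expression(pairs, expr, rule = "either")
  expect_equal(oute$filtered, c(TRUE, TRUE, FALSE))
})

test_that("bias classification applies the strict >2-fold rule on replicate means", {
  meta <- mk_meta()
  pairs <- data.frame(bhd_gene = c("d1", "d2", "d3", "d4", "d5"),
                      bhs_gene = c("s1", "s2", "s3", "s4", "s5"))
  expr <- rbind(mk_expr("d1", meta, 4),  mk_expr("s1", meta, 10),  # 2.5x -> BhS
                mk_expr("d2", meta, 5),  mk_expr("s2", meta, 5),   # equal
                mk_expr("d3", meta, 4),  mk_expr("s3", meta, 8),   # exactly 2x
                mk_expr("d4", meta, 9),  mk_expr("s4", meta, 3),   # 3x -> BhD
                mk_expr("d5", meta, 6),  mk_expr("s5", meta, 0))   # x vs 0
  calls <- heb_classify(pairs, expr, meta)
  expect_equal(calls$call,
               c("BhS_dominant", "neutral", "neutral", "BhD_dominant",
                 "BhD_dominant"))
  expect_equal(calls$log2_ratio[2], 0)
  # 0 vs 0 is neutral
  expr0 <- rbind(mk_expr(c("d1", "s1"), meta, 0),
                 mk_expr(c("d2", "s2"), meta, 40))
  calls0 <- heb_classify(pairs[1:2, ], expr0, meta, tpm_threshold = 0)
  expect_equal(calls0$call[1], "neutral")
})

test_that("bias calls are scale invariant and antisymmetric under label swap", {
  cfg <- sim_config(seed = 9, n_gene_pairs = 300)
  sim <- simulate_expression(cfg)
  calls <- heb_classify(sim$pairs, sim$expr, sim$meta)
  # scale invariance: TPM * 10 with eps scaled alike leaves calls unchanged
  calls10 <- heb_classify(sim$pairs, sim$expr * 10, sim$meta, eps = 1)
  expect_equal(calls10$call, calls$call)
  # label swap: dominant classes exchange, log2 ratios negate exactly
  swapped <- data.frame(bhd_gene = sim$pairs$bhs_gene,
                        bhs_gene = sim$pairs$bhd_gene)
  calls_sw <- heb_classify(swapped, sim$expr, sim$meta)
  expect_equal(calls_sw$log2_ratio, -calls$log2_ratio)
  expect_equal(sum(calls_sw$call == "BhS_dominant"),
               sum(calls$call == "BhD_dominant"))
  expect_equal(sum(calls_sw$call == "BhD_dominant"),
               sum(calls$call == "BhS_dominant"))
  # partition: filtered + neutral + dominant classes = total pairs per group
  tab <- table(calls$group, calls$call)
  expect_true(all(rowSums(tab) == nrow(sim$pairs)))
})

test_that("bias distributions summarise medians and antisymmetry", {
  meta <- mk_meta()
  pairs <- data.frame(bhd_gene = sprintf("d%d", 1:5),
                      bhs_gene = sprintf("s%d", 1:5))
  expr <- rbind(mk_expr(pairs$bhd_gene, meta, 10),
                mk_expr(pairs$bhs_gene, meta, 40))
  calls <- heb_classify(pairs, expr, meta)
  bd <- bias_distribution(calls)
  expect_equal(bd$n_bhs_dominant, 5)
  expect_equal(bd$median_log2_ratio, log2(40.1 / 10.1))
  # mirrored dataset negates the median
  calls_m <- heb_classify(data.frame(bhd_gene = pairs$bhs_gene,
                                     bhs_gene = pairs$bhd_gene), expr, meta)
  expect_equal(bias_distribution(calls_m)$median_log2_ratio,
               -bd$median_log2_ratio)
})

test_that("cross-group consistency separates biased-in-all from consistent", {
  meta <- mk_meta(tissues = c("leaf", "root"))
  pairs <- data.frame(bhd_gene = sprintf("d%d", 1:3),
                      bhs_gene = sprintf("s%d", 1:3))
  # pair 1: BhS everywhere; pair 2: BhS in leaf, BhD in root; pair 3:
  # neutral in root
  expr <- rbind(
    mk_expr("d1", meta, 4),
    mk_expr("s1", meta, 20),
    mk_expr("d2", meta, rep(c(4, 20), each = 3)),
    mk_expr("s2", meta, rep(c(20, 4), each = 3)),
    mk_expr("d3", meta, 4),
    mk_expr("s3", meta, rep(c(20, 4), each = 3)))
  calls <- heb_classify(pairs, expr, meta)
  cons <- consistency_across_groups(calls)
  expect_equal(cons$n_biased_all_groups, 2)
  expect_equal(cons$n_consistent, 1)
  expect_equal(cons$consistent_pairs, "d1|s1")
  expect_equal(cons$pairwise$n_converse, 1)
})

test_that("converse dominance counts direction flips between two groups", {
  cfg <- sim_config(seed = 14, n_gene_pairs = 1000, frac_biased = 0.2,
                    frac_flip = 0.25)
  sim <- simulate_expression(cfg)
  calls <- heb_classify(sim$pairs, sim$expr, sim$meta)
  cv <- converse_dominance(calls, "leaf.well_watered", "leaf.drought")
  expect_equal(cv$n_converse, sum(sim$truth$flip))
  expect_true(all(cv$pairs %in% sim$truth$pair_id[sim$truth$flip]))
  # identical expression in both groups -> zero converse pairs
  cv0 <- converse_dominance(calls, "leaf.well_watered", "root.well_watered")
  expect_equal(cv0$n_converse, 0)
})

test_that("the induction test matches exact rank-sum enumeration at n = 3 + 3", {
  r <- induction_test(c(1, 1, 1), c(100, 110, 120))
  # all treatment ranks above control: one extreme table among choose(6,3)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$fold_change, 110)
  expect_equal(r$direction, "induced")
  r_id <- induction_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r_id$p_value, 1)
  r_sw <- induction_test(c(100, 110, 120), c(1, 1, 1))
  expect_equal(r_sw$p_value, r$p_value)
  expect_equal(r_sw$direction, "repressed")
  expect_error(induction_test(c(1), c(2, 3)), "replicates")
})

test_that("TE flank density does the clipping and coverage arithmetic", {
  gene <- data.frame(chrom = "c1", start = 10000, end = 12000,
                     gene_id = "g1")
  # TE covering exactly the upstream flank of a 2 kb gene with 2 kb flanks
  te_up <- data.frame(chrom = "c1", start = 8000, end = 10000)
  expect_equal(unname(te_flank_density(gene, te_up)), 2000 / 6000)
  # gene body and both flanks fully covered
  te_all <- data.frame(chrom = "c1", start = 0, end = 20000)
  expect_equal(unname(te_flank_density(gene, te_all)), 1)
  # no TEs on the chromosome: 0 with a warning
  te_other <- data.frame(chrom = "c9", start = 0, end = 100)
  expect_warning(d0 <- te_flank_density(gene, te_other), "no TE annotations")
  expect_equal(unname(d0), 0)
  # overlapping TE intervals are merged before counting
  te_ov <- data.frame(chrom = "c1", start = c(8000, 9000), end = c(10000, 11000))
  expect_equal(unname(te_flank_density(gene, te_ov)), 3000 / 6000)
})

test_that("TE-bias association separates the dominant/submissive effect from subgenome", {
  cfg <- sim_config(seed = 31, n_gene_pairs = 500, frac_biased = 1,
                    frac_flip = 0, te_effect = 0.1)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  sp <- data.frame(direction = paste0(tr$direction, "_dominant"),
                   te_density_bhd = tr$te_density_bhd,
                   te_density_bhs = tr$te_density_bhs)
  assoc <- te_bias_association(sp)
  expect_lt(assoc$domsub_test$p_value, 0.01)       # planted Dom < Sub shift
  expect_gt(assoc$subgenome_test$p_value, 0.05)    # no subgenome effect planted
  expect_lt(assoc$domsub_test$median_diff, 0)
  # identical densities within every pair -> signed-rank p = 1
  same <- data.frame(direction = "BhS_dominant",
                     te_density_bhd = seq(0.1, 0.9, length.out = 20),
                     te_density_bhs = seq(0.1, 0.9, length.out = 20))
  expect_equal(te_bias_association(same)$domsub_test$p_value, 1)
  expect_error(te_bias_association(same[1:5, ]), "at least 10")
})

test_that("a planted density-expression correlation of -0.3 is recovered", {
  # the per-draw estimator sd at 5000 genes is ~0.013, so the check is on
  # the mean over three seeded draws (and loosely on each draw)
  rs <- vapply(1:3, function(seed) {
    cfg <- sim_config(seed = seed, n_gene_pairs = 2500, te_effect = 0,
                      te_expr_cor = -0.3)
    sim <- simulate_expression(cfg)
    dens <- te_flank_density(sim$genes, sim$te)
    gene_tbl <- data.frame(mean_tpm = rowMeans(sim$expr),
                           te_density = dens[rownames(sim$expr)])
    assoc <- te_bias_association(
      data.frame(direction = "BhS_dominant",
                 te_density_bhd = stats::runif(20),
                 te_density_bhs = stats::runif(20)),
      gene_tbl = gene_tbl)
    expect_lt(assoc$pearson$p_value, 1e-10)
    assoc$pearson$r
  }, 0)
  expect_lt(abs(mean(rs) - (-0.30)), 0.03)
  expect_true(all(abs(rs - (-0.30)) < 0.05))
})
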