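cfg_small <- synthetic_config(seed = 3, n_tumor = 80, n_normal = 20,
                              n_fragments = 30000)

test_that("generation is deterministic under the config seed", {
  g1 <- make_genome_and_genes(cfg_small)
  g2 <- make_genome_and_genes(cfg_small)
  expect_identical(g1, g2)
  s1 <- simulate_chip(cfg_small, "A", "treated")
  s2 <- simulate_chip(cfg_small, "A", "treated")
  expect_identical(s1, s2)
  c1 <- simulate_cohort(cfg_small, g1$genes)
  c2 <- simulate_cohort(cfg_small, g1$genes)
  expect_identical(c1, c2)
  expect_error(make_genome_and_genes(synthetic_config(
    genome = c(chr1 = 3000, chr2 = 3000))), "too small")
})

test_that("truth tables differ between conditions exactly by the gain loci", {
  par <- simulate_chip(cfg_small, "A", "parental")$truth
  tre <- simulate_chip(cfg_small, "A", "treated")$truth
  extra <- setdiff(tre$locus_id, par$locus_id)
  expect_setequal(tre$role[match(extra, tre$locus_id)],
                  c("shared_gain", "private_gain_A"))
  expect_equal(sum(tre$is_shared_gain), cfg_small$n_shared_gain)
  # shared-gain loci have identical coordinates in both lines' truth
  tre_b <- simulate_chip(cfg_small, "B", "treated")$truth
  sh_a <- tre[tre$is_shared_gain, c("chrom", "start", "end")]
  sh_b <- tre_b[tre_b$is_shared_gain, c("chrom", "start", "end")]
  expect_equal(sh_a, sh_b, ignore_attr = TRUE)
})

test_that("each sample gets exactly the configured fragment budget", {
  for (cond in c("parental", "treated")) {
    sim <- simulate_chip(cfg_small, "B", cond)
    expect_equal(nrow(sim$fragments), cfg_small$n_fragments)
    expect_true(all(sim$fragments$strand %in% c("+", "-")))
  }
})

test_that("planted member peaks stay below the stitch gap; control peaks above", {
  truth <- planted_truth(cfg_small)
  sim <- simulate_chip(cfg_small, "A", "treated")
  for (role in c("base", "control")) {
    locus <- truth[truth$role == role, ][1, ]
    members <- sim$peaks[sim$peaks$chrom == locus$chrom &
                           sim$peaks$start >= locus$start &
                           sim$peaks$end <= locus$end, ]
    members <- members[order(members$start), ]
    gaps <- members$start[-1] - members$end[-nrow(members)]
    if (role == "control") expect_true(all(gaps > 12500))
    else expect_true(all(gaps < 12500))
  }
})

test_that("planted genes sit near shared-gain loci and separate tumor from normal", {
  gg <- make_genome_and_genes(cfg_small)
  cohort <- simulate_cohort(cfg_small, gg$genes)
  expect_length(cohort$planted_genes, cfg_small$n_planted_genes)
  expect_true(all(cohort$planted_genes %in%
                    shared_gain_genes(cfg_small, gg$genes)))
  is_t <- cohort$samples$is_tumor
  diffs <- rowMeans(cohort$expr[cohort$planted_genes, is_t]) -
    rowMeans(cohort$expr[cohort$planted_genes, !is_t])
  expect_equal(unname(diffs), rep(cfg_small$log2_effect, 4), tolerance = 0.35)
})

test_that("tumor-normal shift of planted genes matches the configured effect at scale", {
  cfg <- synthetic_config(seed = 12)  # default 300 tumors / 30 normals
  gg <- make_genome_and_genes(cfg)
  cohort <- simulate_cohort(cfg, gg$genes)
  diffs <- rowMeans(cohort$expr[cohort$planted_genes, cohort$samples$is_tumor]) -
    rowMeans(cohort$expr[cohort$planted_genes, !cohort$samples$is_tumor])
  expect_true(all(abs(diffs - cfg$log2_effect) < 0.3))
})

test_that("a null cohort (no effect, unit hazard ratio) plants nothing detectable", {
  cfg0 <- synthetic_config(seed = 23, n_tumor = 80, n_normal = 20,
                           log2_effect = 0, hazard_ratio = 1)
  gg <- make_genome_and_genes(cfg0)
  cohort <- simulate_cohort(cfg0, gg$genes)
  res <- run_screen(cohort$expr, cohort$samples,
                    genes_of_interest = rownames(cohort$expr))
  # under the null the double filter (upregulation AND survival, each at
  # alpha = 0.05 with the direction constraint) passes well under 5% of genes
  expect_lt(length(res$prognostic_genes), 0.05 * nrow(cohort$expr))
})
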