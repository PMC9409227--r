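test_that("upregulation filter requires direction and Welch significance", {
  set.seed(9)
  n <- 30
  expr <- rbind(
    up = c(rnorm(n, 6, 0.3), rnorm(n, 5, 0.3)),      # planted 2-fold up
    down = c(rnorm(n, 4, 0.3), rnorm(n, 6, 0.3)),    # strongly down
    flat = c(rnorm(n, 5, 0.3), rnorm(n, 5, 0.3)))
  colnames(expr) <- paste0("s", seq_len(2 * n))
  is_tumor <- rep(c(TRUE, FALSE), each = n)
  res <- filter_upregulated(expr, is_tumor)
  expect_true(res$upregulated[res$symbol == "up"])
  expect_false(res$upregulated[res$symbol == "down"])  # tiny p, wrong direction
  expect_lt(res$p[res$symbol == "down"], 1e-6)
  expect_error(filter_upregulated(expr, rep(c(TRUE, FALSE), c(59, 1))),
               "at least 2")
})

test_that("median split sends ties to the low group and rejects constants", {
  expect_equal(median_split(c(a = 1, b = 2, c = 3, d = 4)),
               c(a = FALSE, b = FALSE, c = TRUE, d = TRUE))
  expect_equal(unname(median_split(c(1, 2, 3))), c(FALSE, FALSE, TRUE))
  expect_error(median_split(c(2, 2, 2)), "degenerate")
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  set.seed(21)
  time <- round(rexp(40, 1 / 100), 3)
  km <- kaplan_meier(time, rep(1, 40))
  emp <- vapply(km$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$survival, emp)
  expect_true(all(km$survival <= 1) && km$survival[1] < 1)
})

test_that("log-rank matches the hand-computed hypergeometric statistic", {
  # A: events at 1, 3; B: events at 2, 4; no censoring
  lr <- logrank_test(c(1, 3, 2, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 8 / 13, tolerance = 1e-10)
  # identical groups give statistic 0, p = 1
  lr0 <- logrank_test(c(1, 3, 1, 3), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "event")
})

test_that("survival truncation censors events beyond the horizon", {
  tr <- truncate_survival(c(100, 2000, 1825), c(1, 1, 1), horizon = 1825)
  expect_equal(tr$time, c(100, 1825, 1825))
  expect_equal(tr$event, c(1, 0, 1))
})

test_that("alteration calls are Z >= 0 against the cohort mean", {
  m <- matrix(c(1, 1, 1, 5), 1, dimnames = list("g", paste0("s", 1:4)))
  m2 <- rbind(m, sym = c(1, 2, 4, 5))
  alt <- alteration_matrix(m2)
  expect_equal(unname(alt["g", ]), c(0, 0, 0, 1))
  expect_equal(sum(alt["sym", ]), 2)    # symmetric values: half altered
  expect_error(alteration_matrix(rbind(m2, const = c(3, 3, 3, 3))),
               "zero-variance")
})

test_that("independent half-rate alterations union to about 1 - 0.5^4", {
  set.seed(14)
  n <- 2000
  expr <- matrix(rnorm(4 * n), 4, n,
                 dimnames = list(paste0("g", 1:4), paste0("s", seq_len(n))))
  alt <- alteration_matrix(expr)
  expect_equal(mean(colSums(alt) > 0), 1 - 0.5^4, tolerance = 0.02)
})

test_that("mutual exclusivity scores pairs with Fisher, Haldane OR and BH", {
  m <- matrix(c(rep(1, 10), rep(0, 10),
                rep(1, 10), rep(0, 10)), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:20)))
  res <- mutual_exclusivity(m)
  expect_equal(res$tendency, "co-occurrence")
  expect_equal(res$log2_or, log2((10.5 * 10.5) / (0.5 * 0.5)))
  expect_equal(res$p, oracle_fisher(10, 0, 0, 10), tolerance = 1e-9)
  expect_gte(res$q, res$p)

  set.seed(33)
  big <- matrix(rbinom(6 * 60, 1, 0.5), 6, 60,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:60)))
  res_big <- mutual_exclusivity(big)
  expect_equal(nrow(res_big), choose(6, 2))
  expect_true(all(res_big$q >= res_big$p - 1e-12))
  expect_equal(res_big$q, oracle_bh(res_big$p))
  expect_equal(res_big$tendency == "co-occurrence", res_big$log2_or > 0)
})

test_that("the full screen recovers planted genes and chains all stages", {
  cfg <- synthetic_config(seed = 5, n_tumor = 120, n_normal = 25)
  gg <- make_genome_and_genes(cfg)
  cohort <- simulate_cohort(cfg, gg$genes)
  sets <- list(planted = cohort$planted_genes,
               decoy = setdiff(rownames(cohort$expr),
                               cohort$planted_genes)[1:20])
  res <- run_screen(cohort$expr, cohort$samples,
                    genes_of_interest = c(cohort$planted_genes,
                                          rownames(cohort$expr)[1:10]),
                    gene_sets = sets, n_perm = 200, seed = 4)
  expect_true(all(cohort$planted_genes %in% res$prognostic_genes))
  expect_s3_class(res$exclusivity, "data.frame")
  expect_true(!is.null(res$altered_vs_not$logrank))
  expect_true(all(abs(res$gsea$es) <= 1))
  expect_true(all(res$gsea$fdr >= 0 & res$gsea$fdr <= 1, na.rm = TRUE))
})
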