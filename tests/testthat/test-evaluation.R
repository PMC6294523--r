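test_that("gene-level scoring applies the r^2 >= 0.8 truth-matching rule", {
  # constructed genotypes with controlled LD to the causal SNP
  set.seed(90)
  n <- 600
  causal <- rbinom(n, 2, 0.5)
  perfect <- causal
  high <- ifelse(runif(n) < 0.95, causal, rbinom(n, 2, 0.5))   # r2 ~ 0.9
  low <- ifelse(runif(n) < 0.55, causal, rbinom(n, 2, 0.5))    # r2 ~ 0.5
  indep <- rbinom(n, 2, 0.5)
  G <- toy_G(cbind(causal, perfect, high, low, indep))
  stopifnot(ld_r2(G, "s001", "s003") >= 0.8, ld_r2(G, "s001", "s004") < 0.8)
  truth <- truth_assignments(
    data.frame(gene_id = c("g1", "g2", "g3"),
               snp_id = "s001", beta = 1, coding_mode = "additive",
               stringsAsFactors = FALSE),
    null_gene_ids = c("g4", "g5"))
  calls <- structure(list(esnps = data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    snp_id = c("s001", "s003", "s004", "s005"),
    p_local = 1e-4)), class = "pooled_result")
  calls$egenes <- unique(calls$esnps$gene_id)
  sc <- score_egenes(calls, truth, G)
  # hand tally: g1 exact causal -> TP; g2 via r2~0.9 -> TP;
  # g3 only via r2~0.5 -> FP; g4 null called -> FP
  expect_equal(sc$tp, 2); expect_equal(sc$fp, 2)
  expect_equal(sc$tpr, 2 / 3)
  expect_equal(sc$fdr, 0.5)
  expect_setequal(sc$tp_genes, c("g1", "g2"))
  bad <- calls; bad$esnps$gene_id[1] <- "unknown"
  expect_error(score_egenes(bad, truth, G), "absent from truth")
})

test_that("top-eSNP scoring counts causal and perfect-LD hits", {
  set.seed(91)
  n <- 500
  causal <- rbinom(n, 2, 0.4)
  G <- toy_G(cbind(causal, causal, rbinom(n, 2, 0.4)))
  truth <- truth_assignments(
    data.frame(gene_id = c("g1", "g2"), snp_id = "s001", beta = 1,
               coding_mode = "additive", stringsAsFactors = FALSE),
    null_gene_ids = "g3")
  # g1 top = causal itself; g2 top = perfect proxy s002
  assoc <- toy_assoc(c("g1", "g1", "g2", "g2"),
                     c("s001", "s003", "s002", "s003"),
                     c(1e-8, 0.5, 1e-8, 0.5))
  calls <- structure(list(esnps = data.frame(
    gene_id = c("g1", "g2"), snp_id = c("s001", "s002"), p_local = 1e-6)),
    class = "pooled_result")
  ts <- score_top_esnp(calls, assoc, truth, G)
  expect_equal(ts$causal_rate, 1)
  expect_equal(ts$n_tp, 2L)
})

test_that("estimator scoring reports signed median error and MSE", {
  truth <- truth_assignments(
    data.frame(gene_id = c("g1", "g2", "g3"), snp_id = c("a", "b", "c"),
               beta = c(1, 1, 1), coding_mode = "additive",
               stringsAsFactors = FALSE), character(0))
  est <- structure(list(estimates = data.frame(
    gene_id = c("g1", "g2", "g3"), top_snp_id = c("a", "b", "c"),
    beta_naive = c(1.2, 1.4, 1.1), beta_shrinkage = c(1, 1, 1),
    beta_oos = c(0.9, 1.0, 1.05), beta_weighted = c(1, 1, 1),
    B_e = 10L, correction_undefined = FALSE, stringsAsFactors = FALSE),
    B_total = 10L, weight = 0.632), class = "bootstrap_estimates")
  sc <- score_estimators(est, truth)
  expect_equal(sc$median_error[sc$estimator == "naive"], 0.2)  # overestimate > 0
  expect_equal(sc$median_error[sc$estimator == "shrinkage"], 0)
  expect_equal(sc$mse[sc$estimator == "shrinkage"], 0)
  expect_equal(sc$mse[sc$estimator == "naive"],
               mean(c(0.2, 0.4, 0.1)^2))
})

test_that("scenario runs are deterministic end to end", {
  cfg <- scenario_config(n_samples = 150, causal_maf = 0.25,
                         effects = effect_dist("constant", beta = 1.2),
                         n_genes = 40, n_true_egenes = 15, replicates = 2,
                         n_snps = 1200, region_length = 3e6, seed = 99)
  r1 <- run_scenario(cfg, methods = c("pooled_bh", "bonferroni_bh"))
  r2 <- run_scenario(cfg, methods = c("pooled_bh", "bonferroni_bh"))
  expect_identical(r1$gene_metrics, r2$gene_metrics)
  expect_identical(r1$replicate_counts, r2$replicate_counts)
  # all summary fields populated in the long-format grid output
  grid <- run_scenario_grid(cfg, methods = "bonferroni_bh")
  expect_true(all(c("scenario", "method", "metric", "value") %in%
                    names(grid$summary)))
  expect_true(any(grid$summary$metric == "tpr"))
  # pooled FDR identity: recomputable from the per-replicate counts
  d <- r1$replicate_counts[r1$replicate_counts$method == "pooled_bh", ]
  gm <- r1$gene_metrics[r1$gene_metrics$method == "pooled_bh", ]
  expect_equal(gm$fdr, sum(d$fp) / sum(d$n_called))
  expect_equal(gm$tpr, sum(d$tp) / sum(d$n_true))
})
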