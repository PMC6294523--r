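test_that("a single gene/SNP reduces every step to the nominal p", {
  a <- toy_assoc("g1", "s1", 0.01)
  h <- hierarchical_correct(a, "bh", "bh")
  expect_equal(h$genes$local_min_p, 0.01)
  expect_equal(h$genes$global_p, 0.01)
  expect_true(h$genes$significant)
  expect_equal(h$esnps$snp_id, "s1")
})

test_that("a three-gene toy instance matches the hand-traced three steps", {
  # gene A: 2 SNPs, gene B: 4 SNPs, gene C: 2 SNPs; Bonferroni local, BH global
  a <- toy_assoc(c("gA", "gA", "gB", "gB", "gB", "gB", "gC", "gC"),
                 c("a1", "a2", "b1", "b2", "b3", "b4", "c1", "c2"),
                 c(0.001, 0.04, 0.002, 0.5, 0.6, 0.004, 0.2, 0.9))
  h <- hierarchical_correct(a, "bonferroni", "bh")
  # Step 1 (hand): gA min = 0.001*2 = 0.002; gB min = 0.002*4 = 0.008;
  #                gC min = 0.2*2 = 0.4
  expect_equal(sort(h$genes$local_min_p), c(0.002, 0.008, 0.4))
  # Step 2 (hand BH over {0.002, 0.008, 0.4}): {0.006, 0.012, 0.4}
  expect_equal(sort(h$genes$global_p), c(0.006, 0.012, 0.4))
  expect_setequal(h$genes$gene_id[h$genes$significant], c("gA", "gB"))
  # Step 3 (hand): threshold = max significant local min = 0.008;
  # gA eSNPs with p*2 <= 0.008 -> a1 only; gB with p*4 <= 0.008 -> b1 only
  expect_equal(h$local_threshold, 0.008)
  expect_setequal(h$esnps$snp_id, c("a1", "b1"))

  # no gene passes alpha -> empty sets
  h0 <- hierarchical_correct(toy_assoc(c("g1", "g2"), c("s1", "s2"),
                                       c(0.2, 0.3)), "bonferroni", "bh")
  expect_false(any(h0$genes$significant))
  expect_equal(nrow(h0$esnps), 0L)
  expect_true(is.na(h0$local_threshold))
})

test_that("eigenMT local correction never exceeds plain Bonferroni", {
  sm <- small_sim()
  truth <- select_causal_esnps(sm$G, sm$genes, 0.25, 15, seed = 60)
  E <- simulate_expression(truth, sm$G, seed = 61)
  a <- map_cis(E, sm$G, sm$genes)
  me <- eigenmt_all_genes(sm$G, sm$genes)
  h_e <- hierarchical_correct(a, "eigenmt", "bh", m_eff = me)
  h_b <- hierarchical_correct(a, "bonferroni", "bh")
  expect_true(all(h_e$genes$local_min_p <= h_b$genes$local_min_p + 1e-12))
  expect_true(all(h_e$genes$local_multiplier <= h_b$genes$local_multiplier))
  # hierarchical Bonferroni-BH eGenes are a subset of pooled-BH eGenes
  pooled <- pooled_correct(a, "bh")
  expect_true(all(h_b$genes$gene_id[h_b$genes$significant] %in%
                    pooled$egenes))
  # adjusted p-values stay in (0, 1]
  expect_true(all(h_e$genes$global_p > 0 & h_e$genes$global_p <= 1))
})

test_that("permutation local correction plugs into the hierarchy", {
  sm <- small_sim()
  genes <- sm$genes[1:8, ]
  truth <- truth_assignments(
    data.frame(gene_id = genes$gene_id[1],
               snp_id = sm$G$snp_ids[which.min(abs(sm$G$positions -
                                                     genes$tss[1]))],
               beta = 1.5, coding_mode = "additive",
               stringsAsFactors = FALSE),
    genes$gene_id[-1])
  E <- simulate_expression(truth, sm$G, seed = 62)
  a <- map_cis(E, sm$G, genes)
  perm <- permutation_local_all(E, sm$G, genes, scheme = "beta", B = 200,
                                seed = 63)
  h <- hierarchical_correct(a, "perm", "bh", perm = perm)
  expect_true(h$genes$significant[h$genes$gene_id == genes$gene_id[1]])
  expect_true(genes$gene_id[1] %in% h$esnps$gene_id)
})

test_that("hierarchical BH controls eGene errors under the global null", {
  sm <- small_sim()
  null_truth <- truth_assignments(
    data.frame(gene_id = character(0), snp_id = character(0),
               beta = numeric(0), coding_mode = character(0)),
    sm$genes$gene_id)
  false_calls <- 0
  for (r in 1:5) {
    E <- simulate_expression(null_truth, sm$G, seed = 100 + r)
    a <- map_cis(E, sm$G, sm$genes)
    h <- hierarchical_correct(a, "bonferroni", "bh")
    false_calls <- false_calls + sum(h$genes$significant)
  }
  # BH across genes behaves like FWER control under the complete null:
  # expect ~alpha false eGene calls per replicate at most
  expect_lte(false_calls, 3)
})

test_that("pooled correction reduces to a single-test threshold", {
  one <- toy_assoc("g1", "s1", 0.03)
  pc <- pooled_correct(one, "bh")
  expect_equal(pc$egenes, "g1")
  expect_equal(pc$pairs$p_adjusted, 0.03)
  # empty input -> empty output
  empty <- toy_assoc(character(0), character(0), numeric(0))
  pc0 <- pooled_correct(empty, "bh")
  expect_length(pc0$egenes, 0L)
  # toy instance vs direct formula
  set.seed(64)
  p <- runif(30)^3
  a <- toy_assoc(rep(sprintf("g%d", 1:6), each = 5), sprintf("s%02d", 1:30), p)
  pc <- pooled_correct(a, "bonferroni", alpha = 0.05)
  expect_setequal(pc$pairs$snp_id, sprintf("s%02d", which(p * 30 <= 0.05)))
  expect_error(hierarchical_correct(a, "eigenmt", "bh"), "m_eff")
})
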