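test_that("cis regression equals the closed-form OLS oracle", {
  # toy 8-sample, 1-gene, 1-SNP instance
  y <- c(1.2, 0.3, -0.5, 2.2, 1.1, 0.0, -1.3, 0.8)
  x <- c(0, 1, 2, 2, 1, 0, 0, 1)
  G <- toy_G(matrix(x, ncol = 1))
  genes <- data.frame(gene_id = "g1", chrom = "c", tss = 1000L)
  E <- expression_matrix(rbind(y), "g1")
  a <- map_cis(E, G, genes)
  o <- ols_oracle(y, x)
  expect_equal(a$beta, o$beta, tolerance = 1e-12)
  expect_equal(a$se, o$se, tolerance = 1e-12)
  expect_equal(a$t_stat, o$t, tolerance = 1e-12)
  expect_equal(a$p_nominal, o$p, tolerance = 1e-12)

  # vectorised engine vs per-pair lm on random small instances
  set.seed(20)
  for (rep in 1:3) {
    n <- 30
    dos <- matrix(rbinom(n * 6, 2, runif(6, 0.2, 0.5)), nrow = n)
    Gr <- toy_G(dos)
    yr <- rnorm(n)
    Er <- expression_matrix(rbind(yr), "g1")
    ar <- map_cis(Er, Gr, genes)
    for (j in seq_len(6)) {
      o <- ols_oracle(yr, dos[, j])
      expect_equal(ar$beta[j], o$beta, tolerance = 1e-10)
      expect_equal(ar$p_nominal[j], o$p, tolerance = 1e-10)
    }
  }
})

test_that("p-values are invariant to affine rescaling of expression", {
  set.seed(21)
  n <- 50
  dos <- matrix(rbinom(n * 4, 2, 0.3), nrow = n)
  G <- toy_G(dos)
  genes <- data.frame(gene_id = "g1", chrom = "c", tss = 2000L)
  y <- rnorm(n) + 0.5 * dos[, 2]
  a1 <- map_cis(expression_matrix(rbind(y), "g1"), G, genes)
  a2 <- map_cis(expression_matrix(rbind(3 * y + 7), "g1"), G, genes)
  expect_equal(a1$p_nominal, a2$p_nominal, tolerance = 1e-12)
  expect_equal(3 * a1$beta, a2$beta, tolerance = 1e-12)
})

test_that("the cis window is inclusive at exactly 1 Mb and warns when empty", {
  dos <- matrix(rbinom(60, 2, 0.4), nrow = 20)
  G <- genotype_matrix(dos, c(1e6, 3e6, 3e6 + 1), c("a", "c", "b"))
  genes <- data.frame(gene_id = c("gin", "gout"), chrom = "c",
                      tss = c(2e6, 6e6))
  E <- expression_matrix(matrix(rnorm(40), 2), c("gin", "gout"))
  expect_warning(a <- map_cis(E, G, genes), "no in-window")
  # SNPs at exactly 1 Mb from the TSS are included; 1 Mb + 1 bp is not
  expect_setequal(a$snp_id[a$gene_id == "gin"], c("a", "c"))
  expect_false("gout" %in% a$gene_id)
})

test_that("top association takes the argmin with a genomic-order tie-break", {
  a <- toy_assoc(rep("g1", 3), c("s1", "s2", "s3"), c(0.5, 0.01, 0.2))
  expect_equal(top_association(a, "g1")$snp_id, "s2")
  ties <- toy_assoc(rep("g1", 3), c("s1", "s2", "s3"), c(0.01, 0.5, 0.01))
  ties$distance_to_tss <- c(500L, -100L, -900L)
  expect_equal(top_association(ties, "g1")$snp_id, "s3")
  expect_error(top_association(a, "gX"), "no association")

  # brute-force argmin over a larger gene
  set.seed(22)
  p <- runif(100)
  big <- toy_assoc(rep("g1", 100), sprintf("s%03d", 1:100), p)
  expect_equal(top_association(big, "g1")$snp_id,
               sprintf("s%03d", which.min(p)))
})

test_that("under the global null, nominal p-values are uniform", {
  sm <- small_sim()
  truth <- truth_assignments(
    data.frame(gene_id = character(0), snp_id = character(0),
               beta = numeric(0), coding_mode = character(0)),
    sm$genes$gene_id)
  E <- simulate_expression(truth, sm$G, seed = 23)
  a <- map_cis(E, sm$G, sm$genes)
  # coarse KS check on a thinned subsample (records are LD-correlated)
  set.seed(24)
  p <- sample(a$p_nominal, 400)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 1e-4)
  expect_gt(mean(p), 0.4); expect_lt(mean(p), 0.6)
})
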