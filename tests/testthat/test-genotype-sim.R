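test_that("panel simulation handles degenerate sizes and is deterministic", {
  p1 <- simulate_haplotype_panel(n_haplotypes = 40, n_snps = 1,
                                 region_length = 1000, seed = 3)
  f <- mean(p1$alleles)
  expect_equal(dim(p1$alleles), c(40L, 1L))
  expect_true(f > 0 && f < 1 || f %in% c(0, 1))  # single column, valid freq
  expect_true(all(p1$alleles %in% 0:1))

  a <- simulate_haplotype_panel(n_haplotypes = 30, n_snps = 200,
                                region_length = 1e5, seed = 9)
  b <- simulate_haplotype_panel(n_haplotypes = 30, n_snps = 200,
                                region_length = 1e5, seed = 9)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$positions, b$positions)

  expect_error(simulate_haplotype_panel(n_haplotypes = 1), "n_haplotypes")
  expect_error(simulate_haplotype_panel(n_snps = 0), "n_snps")
})

test_that("mosaic LD decay matches an independent simulation of the process", {
  # package panel and a loop-based oracle re-simulation of the identical
  # copying process, compared on binned mean r^2 (switch rate 1e-4/bp)
  prof <- ld_profile(switch_rate = 1e-4, mutation_rate = 0,
                     gamete_mutation_rate = 0)
  n_snps <- 400
  panel <- simulate_haplotype_panel(n_haplotypes = 250, n_snps = n_snps,
                                    region_length = 2e5, profile = prof,
                                    seed = 21)
  set.seed(22)
  founders_o <- local({
    # oracle founders: same clade construction, re-run independently
    freqs <- exp(runif(n_snps, log(0.005), log(0.5)))
    cl <- eqtlpower:::founder_clades(prof$n_founders)
    t(cl[eqtlpower:::assign_clades(freqs, cl, prof$founder_weights), ])
  })
  oracle <- mosaic_oracle_panel(founders_o, panel$positions, 1e-4, 0,
                                prof$founder_weights, 250)
  breaks <- c(0, 5e3, 1.5e4, 4e4, 1e5, 2e5)
  b_pkg <- binned_r2(panel$alleles, panel$positions, breaks)
  b_ora <- binned_r2(oracle, panel$positions, breaks)
  # same decay profile within Monte-Carlo tolerance
  expect_true(all(abs(b_pkg - b_ora) < 0.06, na.rm = TRUE))
  # and mean r^2 is monotone non-increasing with distance (both)
  expect_true(all(diff(b_pkg) < 0.02, na.rm = TRUE))
})

test_that("genotype sampling respects panel frequencies and dosage domain", {
  # all-zero panel -> all dosages zero
  zero <- structure(list(
    alleles = matrix(0L, 4, 10), positions = 1:10 * 100L,
    snp_ids = sprintf("z%02d", 1:10), profile = ld_profile()),
    class = "haplotype_panel")
  Gz <- sample_genotypes(zero, 20, seed = 1)
  expect_true(all(Gz$dosages == 0L))

  # one-SNP panel at frequency p: sample frequency within binomial 99% CI
  p <- 0.3
  one <- structure(list(
    alleles = matrix(as.integer(runif(200) < p), ncol = 1),
    positions = 50L, snp_ids = "s1",
    profile = ld_profile(gamete_mutation_rate = 0)),
    class = "haplotype_panel")
  p_panel <- mean(one$alleles)
  Gs <- sample_genotypes(one, 5000, seed = 8)
  f <- mean(Gs$dosages) / 2
  ci <- qbinom(c(0.005, 0.995), 10000, p_panel) / 10000
  expect_gte(f, ci[1])
  expect_lte(f, ci[2])

  sm <- small_sim()
  expect_true(all(sm$G$dosages %in% 0:2))
  expect_error(sample_genotypes(sm$panel, 0), "n_samples")
})

test_that("variant QC filters on MAF and HWE exactly", {
  # QC defaults: MAF >= 0.5%, HWE p >= 5e-6
  expect_equal(formals(filter_variants)$maf_min, 0.005)
  expect_equal(formals(filter_variants)$hwe_p_min, 5e-6)

  # 3-SNP toy: SNP2 monomorphic, SNP3 extreme heterozygote excess
  dos <- cbind(c(rep(0, 30), rep(1, 40), rep(2, 30)),
               rep(0, 100),
               rep(1, 100))
  G <- toy_G(dos)
  expect_equal(hwe_test(30, 40, 30), hwe_oracle(30, 40, 30))
  expect_lt(hwe_oracle(0, 100, 0), 5e-6)
  Gf <- filter_variants(G)
  expect_identical(Gf$snp_ids, "s001")

  # idempotence and order preservation on simulated data
  sm <- small_sim()
  Gf2 <- filter_variants(sm$G)
  expect_identical(Gf2$snp_ids, sm$G$snp_ids)
  expect_true(all(diff(match(Gf2$snp_ids, sm$G$snp_ids)) > 0))
})

test_that("ld_r2 is a squared correlation with the expected symmetries", {
  dos <- cbind(c(0, 1, 2, 2, 1, 0), c(0, 1, 2, 2, 1, 0), c(2, 1, 0, 0, 1, 2),
               c(0, 0, 1, 2, 2, 1), rep(1, 6))
  G <- toy_G(dos)
  expect_equal(ld_r2(G, "s001", "s001"), 1)
  expect_equal(ld_r2(G, "s001", "s002"), 1)          # duplicated column
  expect_equal(ld_r2(G, "s001", "s003"), 1)          # coding flip invariance
  expect_equal(ld_r2(G, "s001", "s004"),
               cor(dos[, 1], dos[, 4])^2)             # hand-computable
  expect_equal(ld_r2(G, "s001", "s004"), ld_r2(G, "s004", "s001"))
  expect_error(ld_r2(G, "s001", "s005"), "zero-variance")
})

test_that("causal eSNP selection prunes LD and respects the MAF band", {
  sm <- small_sim()
  truth <- select_causal_esnps(sm$G, sm$genes, maf_target = 0.25,
                               n_causal = 25, seed = 31)
  ent <- truth$entries
  expect_equal(nrow(ent), 25L)
  expect_equal(anyDuplicated(ent$gene_id), 0L)
  expect_equal(length(truth$null_gene_ids), 60L - 25L)
  expect_true(all(ent$beta > 0))

  # brute-force MAF band check (+/- 20% relative)
  mafs <- sm$G$maf[match(ent$snp_id, sm$G$snp_ids)]
  expect_true(all(mafs >= 0.2 & mafs <= 0.3))

  # all pairwise r^2 <= 0.3, exhaustive
  idx <- match(ent$snp_id, sm$G$snp_ids)
  r2 <- cor(sm$G$dosages[, idx])^2
  expect_true(all(r2[upper.tri(r2)] <= 0.3 + 1e-12))

  # every causal SNP within the cis window of its gene
  pos <- sm$G$positions[idx]
  tss <- sm$genes$tss[match(ent$gene_id, sm$genes$gene_id)]
  expect_true(all(abs(pos - tss) <= 1e6))

  # capacity error names the deficit
  expect_error(select_causal_esnps(sm$G, sm$genes, 0.25, n_causal = 1000),
               "capacity")
})

test_that("selection on an independent panel returns uncorrelated SNPs", {
  set.seed(77)
  n <- 400
  dos <- matrix(rbinom(n * 120, 2, 0.3), nrow = n)
  G <- toy_G(dos, positions = seq_len(120) * 2000L)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40), chrom = "c",
                      tss = seq(1000, 239000, length.out = 40))
  noise_bound <- 16 / n  # ~4 sd of a null r^2
  truth <- select_causal_esnps(G, genes, 0.3, n_causal = 10,
                               prune_r2 = noise_bound, maf_tol = 0.9,
                               seed = 5)
  idx <- match(truth$entries$snp_id, G$snp_ids)
  r2 <- cor(G$dosages[, idx])^2
  expect_true(all(r2[upper.tri(r2)] <= noise_bound))
})

test_that("randomness is stream-split and reproducible", {
  expect_identical(split_seed(1, "a"), split_seed(1, "a"))
  expect_false(split_seed(1, "a") == split_seed(1, "b"))
  expect_false(split_seed(1, "a") == split_seed(2, "a"))
  expect_true(split_seed(2147483646, c("rep", 99)) < 2^31)
  # with_seed restores the caller's RNG state
  set.seed(10); before <- .Random.seed
  eqtlpower:::with_seed(99, runif(5))
  expect_identical(.Random.seed, before)
})
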