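test_that("genotype coding follows the additive/dominant/recessive schemes", {
  expect_equal(code_genotype(0:2, "additive"), c(0, 1, 2))
  expect_equal(code_genotype(1, "dominant"), 2)
  expect_equal(code_genotype(0:2, "dominant"), c(0, 2, 2))
  expect_equal(code_genotype(2, "recessive"), 2)
  expect_equal(code_genotype(0:2, "recessive"), c(0, 0, 2))
  expect_equal(code_genotype(0, "recessive"), 0)
  expect_error(code_genotype(1, "codominant"), "unknown")
  expect_error(code_genotype(3, "additive"), "dosage")
})

test_that("expression follows y = beta*g + eps with the requested noise", {
  set.seed(1)
  n <- 10000
  dos <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.1))
  G <- toy_G(dos)
  truth <- truth_assignments(
    data.frame(gene_id = "gA", snp_id = "s001", beta = 1,
               coding_mode = "additive", stringsAsFactors = FALSE),
    null_gene_ids = "gB")

  # degenerate zero-noise option: y exactly beta*g
  E0 <- simulate_expression(truth, G, noise = "none", seed = 2)
  expect_equal(unname(E0$values["gA", ]), as.numeric(dos[, 1]))
  expect_true(all(E0$values["gB", ] == 0))

  # null gene is standard normal; eGene variance matches 2p(1-p)b^2 + 1
  E <- simulate_expression(truth, G, seed = 3)
  expect_lt(abs(mean(E$values["gB", ])), 3 / sqrt(n))
  expect_lt(abs(var(E$values["gB", ]) - 1), 3 * sqrt(2 / n))
  v_expect <- var(dos[, 1]) + 1
  expect_lt(abs(var(E$values["gA", ]) - v_expect), 4 * v_expect / sqrt(n))

  # bit-exact reproducibility; lognormal noise is heavy-tailed
  expect_identical(E$values, simulate_expression(truth, G, seed = 3)$values)
  El <- simulate_expression(truth, G, noise = "lognormal", seed = 4)
  eps <- El$values["gB", ]
  expect_gt(mean((eps - mean(eps))^3) / sd(eps)^3, 2)  # strong right skew

  bad <- truth_assignments(
    data.frame(gene_id = "gA", snp_id = "missing", beta = 1,
               coding_mode = "additive"), "gB")
  expect_error(simulate_expression(bad, G, seed = 1), "absent")
})

test_that("multi-causal genetic variance equals the quadratic form b'Sb", {
  set.seed(9)
  n <- 20000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- ifelse(runif(n) < 0.6, g1, rbinom(n, 2, 0.3))  # correlated causals
  G <- toy_G(cbind(g1, g2))
  beta <- c(0.8, 0.5)
  truth <- truth_assignments(
    data.frame(gene_id = "gA", snp_id = c("s001", "s002"), beta = beta,
               coding_mode = "additive", stringsAsFactors = FALSE),
    character(0))
  E <- simulate_expression(truth, G, seed = 10)
  Sigma <- cov(cbind(g1, g2))
  expected <- drop(t(beta) %*% Sigma %*% beta) + 1
  expect_lt(abs(var(E$values["gA", ]) - expected), 5 * expected / sqrt(n))
})

test_that("correlated blocks share the genetic component with U(0.6,0.9) noise", {
  set.seed(11)
  n <- 10000
  g <- rbinom(n, 2, 0.4)
  G <- toy_G(cbind(g, rbinom(n, 2, 0.2)))
  truth <- truth_assignments(
    data.frame(gene_id = c("g1", "g2", "g3"), snp_id = "s001", beta = 0.7,
               coding_mode = "additive", block = 0L,
               stringsAsFactors = FALSE),
    null_gene_ids = "g4")
  E <- simulate_correlated_blocks(truth, G, seed = 12)
  # noise components have unit variance (algebraic identity r^2 + 1 - r^2)
  for (gg in c("g1", "g2", "g3")) {
    noise <- E$values[gg, ] - 0.7 * g
    expect_lt(abs(var(noise) - 1), 4 * sqrt(2 / n))
  }
  # noise correlation with gene 1 lies in the configured band
  n1 <- E$values["g1", ] - 0.7 * g
  for (gg in c("g2", "g3")) {
    r <- cor(n1, E$values[gg, ] - 0.7 * g)
    expect_gt(r, 0.6 - 4 / sqrt(n))
    expect_lt(r, 0.9 + 4 / sqrt(n))
  }
  # null gene independent of the causal SNP
  expect_lt(abs(cor(E$values["g4", ], g)), 4 / sqrt(n))
})

test_that("block truth assignment gives each block one shared cis eSNP", {
  sm <- small_sim()
  truth <- select_block_truth(sm$G, sm$genes, maf_target = 0.25,
                              n_causal = 20, maf_tol = 0.5, seed = 13)
  ent <- truth$entries
  expect_equal(nrow(ent), 20L)
  for (b in unique(ent$block))
    expect_equal(length(unique(ent$snp_id[ent$block == b])), 1L)
  # the shared SNP lies inside its 1 Mb block
  pos <- sm$G$positions[match(ent$snp_id, sm$G$snp_ids)]
  expect_true(all((pos - 1) %/% 1e6 == ent$block))
})

test_that("secondary causal selection targets a Beta(2.6, 4.5) |r|", {
  expect_equal(eval(formals(select_secondary_causals)$ld_beta_shape),
               c(2.6, 4.5))
  sm <- small_sim()
  primary <- sm$G$snp_ids[which.min(abs(sm$G$maf - 0.3))]
  ids <- select_secondary_causals(sm$G, primary, n_extra = 2, seed = 3)
  expect_length(ids, 2L)
  expect_false(primary %in% ids)
  # nearest-match rule: with target r ~ 0 forced by an uncorrelated pool,
  # the realised |r| tracks the Beta draws as closely as the panel permits
  set.seed(14)
  realised <- target <- numeric(60)
  ip <- match(primary, sm$G$snp_ids)
  nb <- which(abs(sm$G$positions - sm$G$positions[ip]) <= 1e6)
  absr <- abs(as.vector(cor(sm$G$dosages[, ip], sm$G$dosages[, nb])))
  for (k in 1:60) {
    sd <- 1000 + k
    id <- select_secondary_causals(sm$G, primary, 1, seed = sd)
    realised[k] <- abs(cor(sm$G$dosages[, ip],
                           sm$G$dosages[, match(id, sm$G$snp_ids)]))
    target[k] <- eqtlpower:::with_seed(sd, rbeta(1, 2.6, 4.5))
  }
  # each realised |r| is the best available match to its target
  best_gap <- vapply(target, function(t) min(abs(absr[-match(ip, nb)] - t)),
                     numeric(1))
  expect_true(all(abs(abs(realised - target) - best_gap) < 1e-12))
})

test_that("inverse rank normalization maps to qnorm((rank-0.5)/n)", {
  y <- c(3.2, -1, 10, 0.5, 2)
  E <- expression_matrix(rbind(y), "g1")
  out <- inverse_rank_normalize(E)$values[1, ]
  expect_equal(unname(out), qnorm((rank(y) - 0.5) / 5))
  expect_equal(order(out), order(y))  # monotone
  # heavy-tailed input becomes symmetric
  set.seed(15)
  z <- exp(rnorm(2000))
  Ez <- inverse_rank_normalize(expression_matrix(rbind(z), "g1"))$values[1, ]
  expect_lt(abs(mean((Ez - mean(Ez))^3) / sd(Ez)^3), 0.2)
  expect_error(inverse_rank_normalize(expression_matrix(rbind(rep(1, 5)), "g1")),
               "constant")
})
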