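# Independent oracles and small fixture builders used across the test files.
# Everything here is deliberately written as plainly as possible (loops,
# closed forms, stats::lm) so it stays independent of the package's
# vectorised implementations.

# Closed-form simple-regression oracle via stats::lm.
ols_oracle <- function(y, x) {
  fit <- summary(stats::lm(y ~ x))$coefficients
  list(beta = fit[2, 1], se = fit[2, 2], t = fit[2, 3], p = fit[2, 4])
}

# Step-up BH adjustment written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# BY = BH with the harmonic-sum inflation.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  pmin(1, bh_oracle(p) * cm)
}

# Chi-square HWE goodness-of-fit from first principles.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- c(n0, n1, n2)
  stats::pchisq(sum((obs - e)^2 / e), df = 1, lower.tail = FALSE)
}

# Direct (loop-based) re-simulation of the mosaic copying process: an
# independent implementation of the same generative model used as a
# Monte-Carlo oracle for LD decay.
mosaic_oracle_panel <- function(founders, positions, switch_rate,
                                mutation_rate, weights, n_haplotypes) {
  s <- length(positions)
  gaps <- c(0, diff(positions))
  out <- matrix(0L, n_haplotypes, s)
  for (h in seq_len(n_haplotypes)) {
    donor <- sample(nrow(founders), 1, prob = weights)
    for (j in seq_len(s)) {
      if (j > 1 && runif(1) < 1 - exp(-switch_rate * gaps[j]))
        donor <- sample(nrow(founders), 1, prob = weights)
      a <- founders[donor, j]
      if (runif(1) < mutation_rate) a <- 1L - a
      out[h, j] <- a
    }
  }
  out
}

# Mean r^2 by distance bin over all SNP pairs closer than max_d.
binned_r2 <- function(alleles, positions, breaks) {
  m <- ncol(alleles)
  keep <- which(apply(alleles, 2, stats::var) > 0)
  r2 <- d <- numeric(0)
  for (a in seq_along(keep)) {
    j <- keep[a]
    for (b in seq_len(a - 1L)) {
      k <- keep[b]
      dd <- abs(positions[j] - positions[k])
      if (dd >= max(breaks)) next
      r2 <- c(r2, stats::cor(alleles[, j], alleles[, k])^2)
      d <- c(d, dd)
    }
  }
  tapply(r2, cut(d, breaks), mean)
}

# Hand-rolled genotype_matrix from a dosage matrix (positions 1,2,3,...).
toy_G <- function(dos, positions = NULL) {
  dos <- as.matrix(dos)
  if (is.null(positions)) positions <- seq_len(ncol(dos)) * 1000L
  genotype_matrix(dos, positions, sprintf("s%03d", seq_len(ncol(dos))))
}

# Hand-rolled association_table (for hierarchical hand traces).
toy_assoc <- function(gene_id, snp_id, p, n_samples = 100L) {
  k <- length(p)
  out <- data.frame(gene_id = gene_id, snp_id = snp_id, beta = rep(0.1, k),
                    se = rep(0.05, k), t_stat = rep(2, k), p_nominal = p,
                    distance_to_tss = seq_len(k), stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n_samples
  attr(out, "window") <- 1e6
  class(out) <- c("association_table", "data.frame")
  out
}

# Small simulated dataset shared by several fast tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- simulate_haplotype_panel(n_haplotypes = 60, n_snps = 1500,
                                        region_length = 3e6, seed = 5)
      G <- filter_variants(sample_genotypes(panel, 300, seed = 6))
      genes <- simulate_gene_annotation(60, 3e6, seed = 7)
      cache <<- list(panel = panel, G = G, genes = genes)
    }
    cache
  }
})
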