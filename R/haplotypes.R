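#' LD profile of the haplotype-mosaic simulator
#'
#' Parameters of the Li-Stephens-style copying process used to expand a small
#' founder set into a haplotype panel and to resample gametes from the panel.
#' A copied haplotype follows one template until a recombination switch (per-bp
#' rate `switch_rate`, so segments average `1/switch_rate` bp), then jumps to a
#' random template; each copied allele is flipped with probability
#' `mutation_rate`, which both injects rare variation and plays the role of
#' mutation/genotyping error.
#'
#' Founders are not copied uniformly: founder `f` is chosen with weight
#' proportional to `weight_decay^f`, mimicking the unequal haplotype-class
#' frequencies of real populations. Skewed weights spread clade frequencies
#' over a continuum and keep the local effective haplotype diversity low;
#' with equal weights the expected pairwise r^2 collapses to
#' ~1/(n_founders - 1) and no high-LD pairs arise.
#'
#' Defaults (16 founders, decay 0.75 — effective founder number ~7, ~170 kb
#' mean copy segments, panel copy error 1e-3, gamete copy error 1e-4) give
#' blocky LD with high-r^2 proxies around common variants and r^2 decaying
#' towards background over ~100-200 kb, qualitatively matching a small
#' bottlenecked reference panel.
#'
#' @param n_founders number of founder haplotypes (clade-pattern alphabet of
#'   the genealogy, see [simulate_haplotype_panel()]).
#' @param switch_rate per-bp template switch probability of the mosaic.
#' @param mutation_rate per-site allele flip probability when copying a panel
#'   haplotype from the founders.
#' @param gamete_mutation_rate per-site flip probability when resampling
#'   gametes from the panel.
#' @param weight_decay geometric decay of founder copying weights (1 =
#'   uniform copying).
#' @return an object of class `ld_profile`.
#' @export
ld_profile <- function(n_founders = 16L, switch_rate = 6e-6,
                       mutation_rate = 1e-3, gamete_mutation_rate = 1e-4,
                       weight_decay = 0.75) {
  stopifnot(n_founders >= 2, switch_rate >= 0, switch_rate <= 1,
            mutation_rate >= 0, mutation_rate < 0.5,
            gamete_mutation_rate >= 0, gamete_mutation_rate < 0.5,
            weight_decay > 0, weight_decay <= 1)
  w <- weight_decay^seq_len(n_founders)
  structure(list(n_founders = as.integer(n_founders),
                 switch_rate = switch_rate,
                 mutation_rate = mutation_rate,
                 gamete_mutation_rate = gamete_mutation_rate,
                 weight_decay = weight_decay,
                 founder_weights = w / sum(w)),
            class = "ld_profile")
}

#' Allele-frequency spectrum specification
#'
#' @param family `"one_over_p"` (density proportional to 1/p, truncated —
#'   skewed towards rare variants like a sequencing-era site-frequency
#'   spectrum) or `"uniform"`.
#' @param min,max truncation bounds on the founder allele frequency.
#' @return an object of class `maf_spectrum`.
#' @export
maf_spectrum <- function(family = c("one_over_p", "uniform"),
                         min = 0.005, max = 0.5) {
  family <- match.arg(family)
  stopifnot(min > 0, max <= 1, min < max)
  structure(list(family = family, min = min, max = max),
            class = "maf_spectrum")
}

draw_frequencies <- function(spec, n) {
  switch(spec$family,
    one_over_p = exp(stats::runif(n, log(spec$min), log(spec$max))),
    uniform    = stats::runif(n, spec$min, spec$max))
}

# Random founder genealogy: binary tree over n_founders leaves built by
# uniformly random merges. Returns the clade membership matrix (clades x
# founders, root excluded) — every SNP's founder allele pattern is one of
# these clades, so SNP patterns are nested/disjoint clade indicators exactly
# as mutations on a shared genealogy would be.
founder_clades <- function(n_founders) {
  clusters <- as.list(seq_len(n_founders))
  clades <- lapply(seq_len(n_founders), function(i) i)
  while (length(clusters) > 2L) {
    pick <- sample.int(length(clusters), 2L)
    merged <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters <- c(clusters[-pick], list(merged))
    clades[[length(clades) + 1L]] <- merged
  }
  M <- matrix(0L, nrow = length(clades), ncol = n_founders)
  for (k in seq_along(clades)) M[k, clades[[k]]] <- 1L
  M
}

# For each target frequency, sample a clade whose founder-weight is close to
# the target (Gaussian kernel on log frequency), so the realized spectrum
# tracks the requested one while nearby SNPs of similar frequency often share
# a clade (perfect LD) or hit nested clades (high, asymmetric LD).
assign_clades <- function(targets, clade_M, founder_w, kernel_sd = 0.4) {
  cw <- as.vector(clade_M %*% founder_w)
  lcw <- log(cw)
  vapply(targets, function(p) {
    pr <- exp(-(lcw - log(p))^2 / (2 * kernel_sd^2))
    sample.int(length(cw), 1L, prob = pr)
  }, integer(1))
}

# Mosaic-copy haplotypes from a template matrix (compiled kernel).
# templates: haplotypes x SNPs 0/1 matrix; gaps: bp gaps preceding each SNP
# (gaps[1] = 0 so the first SNP always starts a fresh segment); weights:
# optional donor copying weights. Returns n_copies x SNPs.
copy_mosaic <- function(templates, gaps, switch_rate, mutation_rate,
                        weights = NULL, n_copies = 1L) {
  p_switch <- -expm1(-switch_rate * gaps)
  p_switch[1] <- 1
  cumw <- if (is.null(weights)) numeric(0) else cumsum(weights / sum(weights))
  .copy_mosaic_many(templates, p_switch, mutation_rate, cumw, n_copies)
}

#' Simulate an LD-structured haplotype panel
#'
#' Generates a reference panel of phased haplotypes with realistic linkage
#' disequilibrium via a two-layer scheme. Per SNP, a target frequency is
#' drawn from `spectrum` and the founder allele pattern is the clade of a
#' fixed random founder genealogy whose weight best matches that frequency —
#' so founder patterns are nested/disjoint clade indicators, exactly the
#' structure mutations on a shared genealogy produce, giving nearby
#' same-clade SNPs perfect LD and nested clades high asymmetric LD. The panel
#' is then expanded by recombination-mosaic copying from the founders (see
#' [ld_profile()]); correlation decays with inter-SNP distance at the scale
#' set by the switch rate because founder assignments refresh at each
#' recombination segment.
#'
#' SNP positions are uniform over `[1, region_length]`, strictly increasing.
#' Some SNPs may be monomorphic or near-monomorphic in the expanded panel
#' (small clades missed by the copying draw); they are retained here and
#' removed downstream by [filter_variants()].
#'
#' @param n_haplotypes panel size (>= 2).
#' @param n_snps number of SNP sites (>= 1).
#' @param region_length chromosome length in bp.
#' @param profile an [ld_profile()].
#' @param spectrum a [maf_spectrum()].
#' @param seed integer seed; the same seed reproduces the panel bit-exactly.
#' @return object of class `haplotype_panel` with fields `alleles`
#'   (haplotypes x SNPs 0/1 integer matrix), `positions`, `snp_ids`, and the
#'   generating `profile`.
#' @export
simulate_haplotype_panel <- function(n_haplotypes = 100L, n_snps = 26000L,
                                     region_length = 3e7,
                                     profile = ld_profile(),
                                     spectrum = maf_spectrum(),
                                     seed = 1L) {
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (region_length < n_snps) stop("region_length too small for n_snps")
  stopifnot(inherits(profile, "ld_profile"), inherits(spectrum, "maf_spectrum"))
  with_seed(seed, {
    positions <- sort(sample.int(region_length, n_snps))
    freqs <- draw_frequencies(spectrum, n_snps)
    clade_M <- founder_clades(profile$n_founders)
    clade_of <- assign_clades(freqs, clade_M, profile$founder_weights)
    founders <- t(clade_M[clade_of, , drop = FALSE])
    gaps <- c(0, diff(positions))
    alleles <- copy_mosaic(founders, gaps, profile$switch_rate,
                           profile$mutation_rate, profile$founder_weights,
                           n_copies = n_haplotypes)
    structure(list(alleles = alleles,
                   positions = positions,
                   snp_ids = sprintf("snp%06d", seq_len(n_snps)),
                   profile = profile),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs, span %s bp\n",
              nrow(x$alleles), ncol(x$alleles),
              format(max(x$positions), big.mark = ",")))
  invisible(x)
}

#' Construct a genotype matrix object
#'
#' Diploid dosage container used throughout the package. `dosages` counts the
#' coded (ALT/simulated) allele, 0/1/2 per sample; `maf` is the folded
#' frequency `min(f, 1 - f)` recomputed from the dosages, so it is always in
#' `[0, 0.5]` even when the coded allele drifts above 50% in a finite sample.
#' Association statistics and r^2 are invariant to which allele is coded.
#'
#' @param dosages samples x SNPs integer matrix with values in `{0, 1, 2}`.
#' @param positions bp coordinate per SNP (1-based, strictly increasing).
#' @param snp_ids unique SNP identifiers.
#' @param chrom chromosome label (single value).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, positions, snp_ids, chrom = "chrSIM") {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (ncol(dosages) != length(positions) || ncol(dosages) != length(snp_ids))
    stop("dosages, positions and snp_ids disagree on the number of SNPs")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(dosages) && (min(dosages) < 0L || max(dosages) > 2L))
    stop("dosages must be 0, 1 or 2")
  f <- colMeans(dosages) / 2
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages,
                 positions = as.integer(positions),
                 snp_ids = as.character(snp_ids),
                 chrom = chrom,
                 maf = pmin(f, 1 - f)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%s), MAF %.3g-%.3g\n",
    nrow(x$dosages), ncol(x$dosages), x$chrom,
    if (length(x$maf)) min(x$maf) else NA, if (length(x$maf)) max(x$maf) else NA))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Sample diploid genotypes from a haplotype panel
#'
#' Each individual is the sum of two gametes, each an independent
#' recombination-mosaic copy of the panel haplotypes (same switch rate as the
#' panel, small per-site copy error), so arbitrarily many samples can be drawn
#' without duplicating panel haplotypes while preserving the panel's LD
#' structure and allele frequencies in expectation.
#'
#' @param panel a [simulate_haplotype_panel()] result.
#' @param n_samples number of diploid individuals (>= 1).
#' @param seed integer seed.
#' @return a [genotype_matrix()] with rownames `sample0001, ...`.
#' @export
sample_genotypes <- function(panel, n_samples, seed = 1L) {
  if (!inherits(panel, "haplotype_panel")) stop("panel must be a haplotype_panel")
  if (length(panel$positions) == 0L) stop("empty panel")
  if (n_samples < 1) stop("n_samples must be >= 1")
  prof <- panel$profile
  gaps <- c(0, diff(panel$positions))
  with_seed(seed, {
    gam <- copy_mosaic(panel$alleles, gaps, prof$switch_rate,
                       prof$gamete_mutation_rate, n_copies = 2L * n_samples)
    dos <- gam[seq_len(n_samples), , drop = FALSE] +
      gam[n_samples + seq_len(n_samples), , drop = FALSE]
    rownames(dos) <- sprintf("sample%04d", seq_len(n_samples))
    genotype_matrix(dos, panel$positions, panel$snp_ids)
  })
}

# Subset a genotype_matrix by SNP index, preserving invariants.
subset_snps <- function(G, idx) {
  genotype_matrix(G$dosages[, idx, drop = FALSE], G$positions[idx],
                  G$snp_ids[idx], G$chrom)
}

#' Simulate a gene annotation for the synthetic chromosome
#'
#' Transcription start sites are uniform over the region; the default gene
#' count matches a chromosome-22-sized gene set.
#'
#' @param n_genes number of genes.
#' @param region_length chromosome length in bp.
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`.
#' @export
simulate_gene_annotation <- function(n_genes = 618L, region_length = 3e7,
                                     chrom = "chrSIM", seed = 1L) {
  stopifnot(n_genes >= 1, region_length >= n_genes)
  with_seed(seed, {
    tss <- sort(sample.int(region_length, n_genes))
    data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
               chrom = chrom, tss = as.integer(tss),
               stringsAsFactors = FALSE)
  })
}
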