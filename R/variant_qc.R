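#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype counts
#' against Hardy-Weinberg proportions at the sample allele frequency.
#'
#' @param n0,n1,n2 counts of dosage-0, dosage-1 and dosage-2 genotypes
#'   (vectors are accepted and tested elementwise).
#' @return p-value vector; monomorphic sites return 1 (a monomorphic site is
#'   trivially in equilibrium — it is removed by the MAF filter instead).
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- n * 2 * p * q
  e2 <- n * p^2
  chi2 <- ifelse(p == 0 | p == 1, 0,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Variant quality-control filter
#'
#' Removes SNPs with folded minor allele frequency below `maf_min` or with a
#' Hardy-Weinberg equilibrium test p-value below `hwe_p_min`. SNP order is
#' preserved and the operation is idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum MAF retained (default 0.5%).
#' @param hwe_p_min minimum HWE chi-square p-value retained (default 5e-6).
#' @return filtered [genotype_matrix()] (possibly with zero SNPs).
#' @export
filter_variants <- function(G, maf_min = 0.005, hwe_p_min = 5e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$dosages) == 0L) stop("G has no samples")
  cnt <- .dosage_counts(G$dosages)
  keep <- G$maf >= maf_min &
    hwe_test(cnt[1, ], cnt[2, ], cnt[3, ]) >= hwe_p_min
  subset_snps(G, which(keep))
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation between the dosage vectors of two SNPs.
#' Symmetric in its arguments and invariant to allele-coding flips
#' (dosage -> 2 - dosage).
#'
#' @param G a [genotype_matrix()].
#' @param snp_a,snp_b SNP identifiers (or column indices).
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(G, snp_a, snp_b) {
  stopifnot(inherits(G, "genotype_matrix"))
  ia <- resolve_snp(G, snp_a)
  ib <- resolve_snp(G, snp_b)
  xa <- G$dosages[, ia]
  xb <- G$dosages[, ib]
  if (stats::var(xa) == 0 || stats::var(xb) == 0)
    stop("LD undefined: zero-variance SNP")
  stats::cor(xa, xb)^2
}

resolve_snp <- function(G, snp) {
  if (is.numeric(snp)) {
    i <- as.integer(snp)
    if (i < 1 || i > length(G$snp_ids)) stop("SNP index out of range")
    return(i)
  }
  i <- match(snp, G$snp_ids)
  if (is.na(i)) stop(sprintf("unknown SNP id '%s'", snp))
  i
}

# r^2 of one SNP (index) against a set of SNP indices; vectorised.
ld_r2_with <- function(G, idx_one, idx_set) {
  x <- G$dosages[, idx_one]
  if (stats::var(x) == 0) stop("LD undefined: zero-variance SNP")
  as.vector(stats::cor(x, G$dosages[, idx_set, drop = FALSE]))^2
}
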