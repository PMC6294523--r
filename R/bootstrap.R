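#' Bootstrap correction of Winner's Curse in eQTL effect sizes
#'
#' Re-estimates the effect size of each significant eGene's top eSNP through a
#' detection/estimation bootstrap. At each of `B_total` bootstraps the study
#' samples are resampled with replacement to form a *detection group* of the
#' original size; the samples never drawn form the complementary *estimation
#' group*. The gene-top-eSNP slope is re-estimated in both groups. A bootstrap
#' counts towards a gene's `B_e` only when the association is re-detected in
#' the detection group: its nominal p-value there, multiplied by the gene's
#' original local multiplier (cis SNP count for Bonferroni, effective test
#' count for the eigendecomposition correction), must fall below the original
#' analysis' local significance threshold.
#'
#' Three corrected estimators are reported per gene (naive slope
#' `beta_naive` from the full original sample; detection-group and
#' estimation-group slopes `bD_i`, `bE_i` averaged over the `B_e` counted
#' bootstraps):
#'
#' * shrinkage: `beta_naive - mean(bD_i - bE_i)` — the naive estimate minus
#'   the bootstrap estimate of the ascertainment bias;
#' * out-of-sample: `mean(bE_i)`;
#' * weighted: `(1 - w) * beta_naive + w * mean(bE_i)` with `w = 0.632`, the
#'   expected fraction of unique samples in the detection group.
#'
#' Genes never re-detected (`B_e = 0`) keep the naive estimate and are flagged
#' `correction_undefined`.
#'
#' @param E an [expression_matrix()].
#' @param G a [genotype_matrix()].
#' @param hier a [hierarchical_correct()] result with local method
#'   `"bonferroni"` or `"eigenmt"`.
#' @param assoc the `association_table` the correction was computed from
#'   (used to fix each eGene's top eSNP from the original full-sample
#'   analysis).
#' @param B_total number of bootstraps (default 200).
#' @param weight weight of the out-of-sample component (default 0.632).
#' @param seed integer seed; bootstrap b uses the substream
#'   `split_seed(seed, c("boot", b))`, so results do not depend on scheduling.
#' @return object of class `bootstrap_estimates`: data.frame `estimates` with
#'   `gene_id`, `top_snp_id`, `beta_naive`, `beta_shrinkage`, `beta_oos`,
#'   `beta_weighted`, `B_e`, `correction_undefined`; plus `B_total`, `weight`.
#' @export
bootstrap_correct <- function(E, G, hier, assoc, B_total = 200L,
                              weight = 0.632, seed = 1L) {
  stopifnot(inherits(hier, "hierarchical_result"))
  if (!hier$local_method %in% c("bonferroni", "eigenmt"))
    stop("bootstrap correction requires a Bonferroni-type local correction")
  sig <- hier$genes[hier$genes$significant, ]
  if (!nrow(sig)) stop("no significant eGenes with a top eSNP")
  thr <- hier$local_threshold
  n <- ncol(E$values)

  genes <- sig$gene_id
  top <- vapply(genes, function(g) top_association(assoc, g)$snp_id,
                character(1))
  mult <- stats::setNames(sig$local_multiplier, genes)
  Yg <- E$values[genes, , drop = FALSE]
  Xg <- G$dosages[, top, drop = FALSE] * 1.0

  naive <- vapply(seq_along(genes), function(k)
    slope_p(Yg[k, ], Xg[, k])$beta, numeric(1))

  sumD <- sumE <- Be <- stats::setNames(numeric(length(genes)), genes)
  skipped <- 0L
  for (b in seq_len(B_total)) {
    with_seed(split_seed(seed, c("boot", b)), {
      det <- sample.int(n, n, replace = TRUE)
      est <- setdiff(seq_len(n), unique(det))
      if (!length(est)) {
        skipped <- skipped + 1L
      } else {
        for (k in seq_along(genes)) {
          fd <- slope_p(Yg[k, det], Xg[det, k])
          if (is.na(fd$p)) next
          if (min(1, fd$p * mult[[genes[k]]]) <= thr) {
            fe <- slope_p(Yg[k, est], Xg[est, k])
            if (is.na(fe$beta)) next
            Be[k] <- Be[k] + 1
            sumD[k] <- sumD[k] + fd$beta
            sumE[k] <- sumE[k] + fe$beta
          }
        }
      }
    })
  }
  if (skipped)
    warning(sprintf("%d bootstrap(s) skipped: empty estimation group", skipped))

  undef <- Be == 0
  mD <- ifelse(undef, NA_real_, sumD / Be)
  mE <- ifelse(undef, NA_real_, sumE / Be)
  est <- data.frame(
    gene_id = genes, top_snp_id = top,
    beta_naive = naive,
    beta_shrinkage = ifelse(undef, naive, naive - (mD - mE)),
    beta_oos = ifelse(undef, naive, mE),
    beta_weighted = ifelse(undef, naive, (1 - weight) * naive + weight * mE),
    B_e = as.integer(Be),
    correction_undefined = undef,
    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  structure(list(estimates = est, B_total = as.integer(B_total),
                 weight = weight, local_method = hier$local_method),
            class = "bootstrap_estimates")
}

#' @export
print.bootstrap_estimates <- function(x, ...) {
  cat(sprintf(
    "bootstrap_estimates: %d eGenes, %d bootstraps, median B_e = %g\n",
    nrow(x$estimates), x$B_total, stats::median(x$estimates$B_e)))
  invisible(x)
}

# Simple-regression slope and p for one gene/SNP pair on a sample subset.
slope_p <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  if (n < 4 || sxx == 0) return(list(beta = NA_real_, p = NA_real_))
  xc <- x - mean(x)
  yc <- y - mean(y)
  b <- sum(xc * yc) / sxx
  rss <- max(sum(yc^2) - b * sum(xc * yc), 0)
  se2 <- rss / (n - 2) / sxx
  if (se2 == 0) return(list(beta = b, p = 0))
  list(beta = b, p = 2 * stats::pt(-abs(b) / sqrt(se2), n - 2))
}

#' Expected unique-sample fraction of an n-out-of-n bootstrap resample
#'
#' Monte-Carlo mean over `B` resamples of the fraction of distinct samples in
#' a with-replacement resample of size `n`; the expectation is
#' `1 - (1 - 1/n)^n`, which converges to `1 - 1/e ~ 0.632` — the weight used
#' by the weighted bootstrap estimator.
#'
#' @param n sample size (>= 1).
#' @param B number of Monte-Carlo resamples.
#' @param seed integer seed.
#' @return list with `fraction` (Monte-Carlo mean) and `expected` (closed
#'   form).
#' @export
expected_unique_fraction <- function(n, B = 1000L, seed = 1L) {
  stopifnot(n >= 1, B >= 1)
  frac <- with_seed(seed, {
    mean(vapply(seq_len(B), function(b)
      length(unique(sample.int(n, n, replace = TRUE))) / n, numeric(1)))
  })
  list(fraction = frac, expected = 1 - (1 - 1 / n)^n)
}
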