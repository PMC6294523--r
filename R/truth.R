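#' Effect-size distribution specification
#'
#' True eGene effect sizes are either drawn from a gamma distribution (the
#' default stand-in for an empirical cis-eQTL effect-size distribution: mostly
#' small effects with a long tail) or held constant across genes (the
#' constant-effect power grids use 0.25, 0.5, 1 or 1.5 s.d. expression per
#' allele).
#'
#' @param family `"gamma"` or `"constant"`.
#' @param shape,scale gamma parameters (defaults 1.8 and 0.35).
#' @param beta constant effect size, s.d. expression per allele.
#' @return object of class `effect_dist`.
#' @export
effect_dist <- function(family = c("gamma", "constant"),
                        shape = 1.8, scale = 0.35, beta = 1) {
  family <- match.arg(family)
  stopifnot(shape > 0, scale > 0, beta > 0)
  structure(list(family = family, shape = shape, scale = scale, beta = beta),
            class = "effect_dist")
}

draw_effects <- function(dist, n) {
  stopifnot(inherits(dist, "effect_dist"))
  if (dist$family == "gamma") {
    b <- stats::rgamma(n, shape = dist$shape, scale = dist$scale)
    pmax(b, 1e-8)  # strictly positive
  } else rep(dist$beta, n)
}

#' Construct a truth-assignment object
#'
#' The simulation ground truth: which genes are true eGenes, their causal
#' eSNP(s), effect sizes and genotype coding mode. `entries` is in long format
#' (one row per causal SNP, so multi-causal genes occupy several rows).
#'
#' @param entries data.frame with columns `gene_id`, `snp_id`, `beta`
#'   (positive), `coding_mode` (`"additive"`, `"dominant"` or `"recessive"`).
#' @param null_gene_ids genes simulated with no genetic effect.
#' @return object of class `truth_assignments`.
#' @export
truth_assignments <- function(entries, null_gene_ids) {
  stopifnot(is.data.frame(entries),
            all(c("gene_id", "snp_id", "beta", "coding_mode") %in%
                  names(entries)))
  if (nrow(entries) && any(entries$beta <= 0))
    stop("true eGene effect sizes must be positive")
  if (!all(entries$coding_mode %in% c("additive", "dominant", "recessive")))
    stop("unknown coding_mode")
  if (any(entries$gene_id %in% null_gene_ids))
    stop("a gene cannot be both a true eGene and a null gene")
  structure(list(entries = entries,
                 null_gene_ids = as.character(null_gene_ids)),
            class = "truth_assignments")
}

#' @export
print.truth_assignments <- function(x, ...) {
  cat(sprintf("truth_assignments: %d true eGenes (%d causal SNPs), %d null genes\n",
              length(unique(x$entries$gene_id)), nrow(x$entries),
              length(x$null_gene_ids)))
  invisible(x)
}

true_egene_ids <- function(truth) unique(truth$entries$gene_id)
all_gene_ids <- function(truth) c(true_egene_ids(truth), truth$null_gene_ids)

#' Select causal eSNPs at a target MAF from an LD-pruned subset
#'
#' Designates `n_causal` genes as true eGenes, each regulated by one causal
#' eSNP within +/- `window` bp of its TSS. Candidate SNPs have MAF within a
#' relative tolerance band of `maf_target`; candidates are visited in random
#' order and accepted greedily provided their r^2 with every already-selected
#' causal SNP is at most `prune_r2` (LD pruning) and at least one unused gene's
#' cis window covers them. The remaining genes become null genes. Effect sizes
#' are drawn from `effects`.
#'
#' @param G a filtered [genotype_matrix()].
#' @param genes gene annotation (`gene_id`, `chrom`, `tss`).
#' @param maf_target scenario causal MAF.
#' @param n_causal number of true eGenes (default 200).
#' @param prune_r2 maximum pairwise r^2 among causal SNPs (default 0.3).
#' @param maf_tol relative MAF tolerance band (default 0.2: target 5% accepts
#'   4-6%).
#' @param effects an [effect_dist()].
#' @param coding_mode genotype coding of the causal SNPs.
#' @param window cis-window half-width in bp (inclusive).
#' @param seed integer seed.
#' @return a [truth_assignments()].
#' @export
select_causal_esnps <- function(G, genes, maf_target, n_causal = 200L,
                                prune_r2 = 0.3, maf_tol = 0.2,
                                effects = effect_dist(),
                                coding_mode = "additive",
                                window = 1e6, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), is.data.frame(genes))
  band <- maf_target * c(1 - maf_tol, 1 + maf_tol)
  cand <- which(G$maf >= band[1] & G$maf <= pmin(band[2], 0.5))
  if (length(cand) < n_causal)
    stop(sprintf(
      "capacity: only %d SNPs within %.3g-%.3g MAF band, need %d",
      length(cand), band[1], min(band[2], 0.5), n_causal))
  with_seed(seed, {
    cand <- sample(cand)
    n <- nrow(G$dosages)
    kept_idx <- integer(0)
    kept_gene <- character(0)
    kept_scaled <- matrix(0, nrow = n, ncol = 0)
    used_gene <- logical(nrow(genes))
    for (j in cand) {
      if (length(kept_idx) >= n_causal) break
      pos <- G$positions[j]
      elig <- which(!used_gene & abs(genes$tss - pos) <= window)
      if (!length(elig)) next
      x <- G$dosages[, j]
      sdx <- stats::sd(x)
      if (sdx == 0) next
      xs <- (x - mean(x)) / (sdx * sqrt(n - 1))
      if (ncol(kept_scaled)) {
        r2 <- as.vector(crossprod(kept_scaled, xs))^2
        if (max(r2) > prune_r2) next
      }
      g <- if (length(elig) == 1L) elig else sample(elig, 1L)
      used_gene[g] <- TRUE
      kept_idx <- c(kept_idx, j)
      kept_gene <- c(kept_gene, genes$gene_id[g])
      kept_scaled <- cbind(kept_scaled, xs)
    }
    if (length(kept_idx) < n_causal)
      stop(sprintf(
        "capacity: selected only %d of %d causal eSNPs after LD pruning and gene assignment",
        length(kept_idx), n_causal))
    betas <- draw_effects(effects, n_causal)
    entries <- data.frame(gene_id = kept_gene,
                          snp_id = G$snp_ids[kept_idx],
                          beta = betas,
                          coding_mode = coding_mode,
                          stringsAsFactors = FALSE)
    truth_assignments(entries,
                      setdiff(genes$gene_id, kept_gene))
  })
}

#' Select secondary causal eSNPs in LD with a primary causal eSNP
#'
#' For multi-causal simulations, each additional causal eSNP is chosen so that
#' the absolute dosage correlation with the primary causal eSNP matches a
#' target drawn from a Beta(2.6, 4.5) distribution (an empirical model of the
#' LD between independently associated eSNPs of one gene) as closely as the
#' available SNPs permit: the in-window SNP minimising `||r| - r_target|` is
#' taken, excluding SNPs already causal.
#'
#' @param G a [genotype_matrix()].
#' @param primary_snp id or index of the primary causal eSNP.
#' @param n_extra number of additional causal eSNPs (1 or 2).
#' @param ld_beta_shape two Beta shape parameters (default `c(2.6, 4.5)`).
#' @param window search window in bp around the primary SNP.
#' @param exclude SNP ids never to select (e.g. other genes' causals).
#' @param seed integer seed.
#' @return character vector of selected SNP ids.
#' @export
select_secondary_causals <- function(G, primary_snp, n_extra = 1L,
                                     ld_beta_shape = c(2.6, 4.5),
                                     window = 1e6, exclude = character(0),
                                     seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), n_extra %in% 1:2)
  ip <- resolve_snp(G, primary_snp)
  pos <- G$positions[ip]
  nb <- which(abs(G$positions - pos) <= window)
  nb <- setdiff(nb, c(ip, match(exclude, G$snp_ids)))
  nb <- nb[apply(G$dosages[, nb, drop = FALSE], 2, stats::var) > 0]
  if (!length(nb)) stop("capacity: primary SNP has no in-window neighbours")
  absr <- abs(as.vector(stats::cor(G$dosages[, ip],
                                   G$dosages[, nb, drop = FALSE])))
  with_seed(seed, {
    chosen <- integer(0)
    for (k in seq_len(n_extra)) {
      target <- stats::rbeta(1, ld_beta_shape[1], ld_beta_shape[2])
      ok <- setdiff(seq_along(nb), chosen)
      if (!length(ok)) stop("capacity: not enough distinct neighbours")
      pick <- ok[which.min(abs(absr[ok] - target))]
      chosen <- c(chosen, pick)
    }
    G$snp_ids[nb[chosen]]
  })
}

#' Add secondary causal eSNPs to every true eGene of a truth object
#'
#' Convenience wrapper around [select_secondary_causals()] for the
#' multi-causal (2 or 3 eSNPs per eGene) simulation variants; effect sizes of
#' the extra SNPs are drawn from `effects`.
#'
#' @inheritParams select_secondary_causals
#' @param truth a single-causal [truth_assignments()].
#' @param effects an [effect_dist()].
#' @return a new [truth_assignments()] in long format.
#' @export
add_secondary_causals <- function(truth, G, n_extra = 1L,
                                  ld_beta_shape = c(2.6, 4.5),
                                  window = 1e6, effects = effect_dist(),
                                  seed = 1L) {
  stopifnot(inherits(truth, "truth_assignments"))
  ent <- truth$entries
  if (any(duplicated(ent$gene_id)))
    stop("add_secondary_causals expects a single-causal truth object")
  extra <- vector("list", nrow(ent))
  with_seed(seed, {
    for (i in seq_len(nrow(ent))) {
      ids <- select_secondary_causals(
        G, ent$snp_id[i], n_extra, ld_beta_shape, window,
        exclude = c(ent$snp_id, unlist(lapply(extra, `[[`, "snp_id"))),
        seed = sample.int(.Machine$integer.max %/% 2, 1))
      extra[[i]] <- data.frame(gene_id = ent$gene_id[i], snp_id = ids,
                               beta = draw_effects(effects, length(ids)),
                               coding_mode = ent$coding_mode[i],
                               stringsAsFactors = FALSE)
    }
  })
  truth_assignments(rbind(ent, do.call(rbind, extra)), truth$null_gene_ids)
}
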