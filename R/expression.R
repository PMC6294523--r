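#' Recoding of genotype dosages for non-additive causal effects
#'
#' Additive effects use the raw dosage (0, 1, 2); dominant effects code the
#' presence of one or more coded alleles as (0, 2, 2); recessive effects code
#' homozygotes only as (0, 0, 2).
#'
#' @param dosage dosage vector with values in `{0, 1, 2}`.
#' @param mode `"additive"`, `"dominant"` or `"recessive"`.
#' @return recoded numeric vector.
#' @examples
#' code_genotype(0:2, "dominant")   # 0 2 2
#' code_genotype(0:2, "recessive")  # 0 0 2
#' @export
code_genotype <- function(dosage, mode) {
  if (any(!dosage %in% 0:2)) stop("dosage values must be 0, 1 or 2")
  switch(mode,
         additive  = as.numeric(dosage),
         dominant  = c(0, 2, 2)[dosage + 1],
         recessive = c(0, 0, 2)[dosage + 1],
         stop(sprintf("unknown coding mode '%s'", mode)))
}

#' Construct an expression matrix object
#'
#' @param values genes x samples numeric matrix (no missing values).
#' @param gene_ids unique gene identifiers (rownames are set to these).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids) {
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids))
    stop("values and gene_ids disagree on the number of genes")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyNA(values)) stop("expression values must not be missing")
  rownames(values) <- gene_ids
  structure(list(values = values, gene_ids = as.character(gene_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate gene expression under the generative cis-eQTL model
#'
#' Each true eGene follows `y = sum_k beta_k * g_k + eps` where `g_k` is the
#' (possibly dominant/recessive recoded) dosage of its causal eSNP(s); null
#' genes are pure noise (`beta = 0`). Noise `eps` is standard normal by
#' default, log-normal (log-mean 0, log-sd 1) to probe the normality
#' assumption, or exactly zero (`"none"`, for degenerate-input checks).
#'
#' @param truth a [truth_assignments()].
#' @param G a [genotype_matrix()] containing every causal SNP.
#' @param noise `"normal"`, `"lognormal"` or `"none"`.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return an [expression_matrix()] over all genes in `truth` (true eGenes
#'   first, then null genes) with `G`'s samples as columns.
#' @export
simulate_expression <- function(truth, G, noise = c("normal", "lognormal", "none"),
                                seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "truth_assignments"),
            inherits(G, "genotype_matrix"))
  miss <- setdiff(truth$entries$snp_id, G$snp_ids)
  if (length(miss))
    stop(sprintf("causal SNP(s) absent from genotypes: %s",
                 paste(utils::head(miss, 3), collapse = ", ")))
  genes <- all_gene_ids(truth)
  n <- nrow(G$dosages)
  with_seed(seed, {
    E <- matrix(0, nrow = length(genes), ncol = n,
                dimnames = list(genes, rownames(G$dosages)))
    ent <- truth$entries
    for (i in seq_len(nrow(ent))) {
      g <- code_genotype(G$dosages[, ent$snp_id[i]], ent$coding_mode[i])
      E[ent$gene_id[i], ] <- E[ent$gene_id[i], ] + ent$beta[i] * g
    }
    if (noise != "none") {
      eps <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes))
      if (noise == "lognormal") eps <- exp(eps)
      E <- E + eps
    }
    expression_matrix(E, genes)
  })
}

#' Co-expression block specification
#'
#' @param block_length genomic block length in bp (default 1 Mb).
#' @param r_low,r_high bounds of the uniform distribution the within-block
#'   noise correlation is drawn from (defaults 0.6 and 0.9).
#' @return object of class `coexpression_spec`.
#' @export
coexpression_spec <- function(block_length = 1e6, r_low = 0.6, r_high = 0.9) {
  stopifnot(block_length > 0, r_low >= 0, r_low <= r_high, r_high < 1)
  structure(list(block_length = block_length, r_low = r_low, r_high = r_high),
            class = "coexpression_spec")
}

#' Assign block-shared causal eSNPs for the correlated-expression model
#'
#' Bins genes by TSS into consecutive blocks of `spec$block_length` bp from
#' the chromosome start, designates `n_causal` random genes as true eGenes,
#' and assigns each occupied block one shared causal eSNP drawn from the
#' scenario MAF band inside the block (so it is cis to every gene of the
#' block); all true eGenes of a block get the block's effect size.
#'
#' @inheritParams select_causal_esnps
#' @param spec a [coexpression_spec()].
#' @return a [truth_assignments()] whose entries carry a `block` column.
#' @export
select_block_truth <- function(G, genes, maf_target, n_causal = 200L,
                               spec = coexpression_spec(), maf_tol = 0.2,
                               effects = effect_dist(), seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), is.data.frame(genes))
  band <- maf_target * c(1 - maf_tol, 1 + maf_tol)
  with_seed(seed, {
    egenes <- sort(sample.int(nrow(genes), n_causal))
    block <- (genes$tss[egenes] - 1) %/% spec$block_length
    entries <- NULL
    for (b in unique(block)) {
      gb <- egenes[block == b]
      lo <- b * spec$block_length + 1
      hi <- lo + spec$block_length - 1
      cand <- which(G$positions >= lo & G$positions <= hi &
                      G$maf >= band[1] & G$maf <= pmin(band[2], 0.5))
      if (!length(cand))
        stop(sprintf("capacity: no SNP in MAF band within block %d", b))
      snp <- G$snp_ids[sample(cand, 1L)]
      beta <- draw_effects(effects, 1L)
      entries <- rbind(entries, data.frame(
        gene_id = genes$gene_id[gb], snp_id = snp, beta = beta,
        coding_mode = "additive", block = b, stringsAsFactors = FALSE))
    }
    truth_assignments(entries, setdiff(genes$gene_id, entries$gene_id))
  })
}

#' Simulate correlated co-expression blocks
#'
#' True eGenes inside one genomic block share a single causal eSNP and a
#' common genetic component `beta_j * g_j`; the noise of each gene after the
#' first is `r_i * eps_1 + sqrt(1 - r_i^2) * eps_i`, which has unit variance
#' and correlation `r_i ~ U(r_low, r_high)` with the first gene's noise.
#' Null genes receive independent standard-normal noise. Blocks with no true
#' eGene are skipped silently.
#'
#' @param truth a [select_block_truth()] result (entries must carry `block`).
#' @param G a [genotype_matrix()].
#' @param spec the [coexpression_spec()] used for block assignment.
#' @param seed integer seed.
#' @return an [expression_matrix()].
#' @export
simulate_correlated_blocks <- function(truth, G, spec = coexpression_spec(),
                                       seed = 1L) {
  stopifnot(inherits(truth, "truth_assignments"),
            !is.null(truth$entries$block))
  ent <- truth$entries
  genes <- all_gene_ids(truth)
  n <- nrow(G$dosages)
  with_seed(seed, {
    E <- matrix(0, nrow = length(genes), ncol = n,
                dimnames = list(genes, rownames(G$dosages)))
    for (b in unique(ent$block)) {
      rows <- which(ent$block == b)
      g <- G$dosages[, ent$snp_id[rows[1]]]
      genetic <- ent$beta[rows[1]] * g
      eps1 <- stats::rnorm(n)
      for (k in seq_along(rows)) {
        gid <- ent$gene_id[rows[k]]
        if (k == 1L) {
          E[gid, ] <- genetic + eps1
        } else {
          r <- stats::runif(1, spec$r_low, spec$r_high)
          E[gid, ] <- genetic + r * eps1 + sqrt(1 - r^2) * stats::rnorm(n)
        }
      }
    }
    for (gid in truth$null_gene_ids) E[gid, ] <- stats::rnorm(n)
    expression_matrix(E, genes)
  })
}

#' Inverse rank normal transformation
#'
#' Per gene, replaces expression values by the normal quantiles of their
#' adjusted ranks, `qnorm((rank - 0.5) / n)` with average ranks for ties, so
#' each gene's transformed profile is symmetric with mean ~0 regardless of the
#' original distribution. Rank order is preserved.
#'
#' @param E an [expression_matrix()].
#' @return transformed [expression_matrix()].
#' @export
inverse_rank_normalize <- function(E) {
  stopifnot(inherits(E, "expression_matrix"))
  n <- ncol(E$values)
  out <- t(apply(E$values, 1, function(y) {
    if (max(y) == min(y)) stop("cannot rank-normalize a constant gene")
    stats::qnorm((rank(y, ties.method = "average") - 0.5) / n)
  }))
  expression_matrix(out, E$gene_ids)
}
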