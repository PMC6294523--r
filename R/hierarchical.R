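#' Hierarchical three-step multiple-testing correction
#'
#' Implements the two-level correction for cis-eQTL mapping:
#'
#' * **Step 1 (local):** within each gene, nominal p-values of all cis SNPs
#'   are adjusted for the multiple SNPs tested — by an FDR procedure
#'   (`"st"`, `"bh"`, `"by"`), Bonferroni (`"bonferroni"`, multiplier = number
#'   of cis SNPs), the eigendecomposition-based effective-test Bonferroni
#'   (`"eigenmt"`, multiplier = `m_eff`), or a permutation scheme (`"perm"`,
#'   supplying one gene-level permutation p-value; see
#'   [permutation_local_all()]).
#' * **Step 2 (global):** the minimum locally adjusted p-value of each gene is
#'   adjusted across genes by `global_method` (`"st"`, `"bh"`, `"by"` or
#'   `"bonferroni"`); genes with globally adjusted p <= `alpha` are the
#'   significant eGenes.
#' * **Step 3 (eSNPs):** the local significance threshold is the largest
#'   gene-level minimum locally adjusted p-value among significant eGenes;
#'   for each significant eGene, SNPs whose locally adjusted p-value does not
#'   exceed that threshold are its significant eSNPs (the boundary eGene thus
#'   keeps its top eSNP).
#'
#' @param assoc an `association_table` from [map_cis()].
#' @param local_method one of `"st"`, `"bh"`, `"by"`, `"bonferroni"`,
#'   `"eigenmt"`, `"perm"`.
#' @param global_method one of `"st"`, `"bh"`, `"by"`, `"bonferroni"`.
#' @param alpha global significance level (default 0.05).
#' @param m_eff named per-gene effective test counts, required for
#'   `local_method = "eigenmt"` (see [eigenmt_all_genes()]).
#' @param perm named per-gene list of [permutation_local()] results, required
#'   for `local_method = "perm"`.
#' @return object of class `hierarchical_result`: `genes` (per-gene
#'   `local_min_p`, `global_p`, `significant`, `n_cis_snps`, `local_multiplier`),
#'   `esnps` (`gene_id`, `snp_id`, `p_local` for significant eGenes),
#'   `local_threshold`, `alpha` and the method tags.
#' @export
hierarchical_correct <- function(assoc,
                                 local_method = c("eigenmt", "bonferroni",
                                                  "bh", "by", "st", "perm"),
                                 global_method = c("bh", "st", "by",
                                                   "bonferroni"),
                                 alpha = 0.05, m_eff = NULL, perm = NULL) {
  local_method <- match.arg(local_method)
  global_method <- match.arg(global_method)
  stopifnot(inherits(assoc, "association_table") || is.data.frame(assoc))
  rows <- assoc_gene_rows(assoc)
  gene_ids <- names(rows)
  if (local_method == "eigenmt") {
    if (is.null(m_eff) || !all(gene_ids %in% names(m_eff)))
      stop("local_method 'eigenmt' needs a named m_eff vector covering all genes")
  }
  if (local_method == "perm") {
    if (is.null(perm) || !all(gene_ids %in% names(perm)))
      stop("local_method 'perm' needs a named list of permutation results")
  }

  m_cis <- lengths(rows)
  mult <- rep(NA_real_, length(gene_ids))
  local_min <- numeric(length(gene_ids))
  p_local_list <- vector("list", length(gene_ids))
  for (k in seq_along(gene_ids)) {
    gid <- gene_ids[k]
    p <- assoc$p_nominal[rows[[k]]]
    pl <- switch(local_method,
      bonferroni = { mult[k] <- m_cis[k]; pmin(1, p * m_cis[k]) },
      eigenmt    = { mult[k] <- m_eff[[gid]]; pmin(1, p * m_eff[[gid]]) },
      bh = adjust_bh(p),
      by = adjust_by(p),
      st = adjust_st(p),
      perm = {
        pr <- perm[[gid]]
        stats::setNames(pr$p_local[assoc$snp_id[rows[[k]]]], NULL)
      })
    p_local_list[[k]] <- pl
    local_min[k] <- if (local_method == "perm") perm[[gid]]$p_perm else min(pl)
  }

  global_p <- adjust_method(local_min, global_method)
  significant <- global_p <= alpha
  local_threshold <- if (any(significant)) max(local_min[significant]) else NA_real_

  esnps <- NULL
  if (any(significant)) {
    keep <- which(significant)
    esnps <- do.call(rbind, lapply(keep, function(k) {
      sel <- which(p_local_list[[k]] <= local_threshold)
      if (!length(sel)) return(NULL)
      data.frame(gene_id = gene_ids[k],
                 snp_id = assoc$snp_id[rows[[k]][sel]],
                 p_local = p_local_list[[k]][sel],
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(esnps))
    esnps <- data.frame(gene_id = character(0), snp_id = character(0),
                        p_local = numeric(0), stringsAsFactors = FALSE)

  structure(list(
    genes = data.frame(gene_id = gene_ids, local_min_p = local_min,
                       global_p = global_p, significant = significant,
                       n_cis_snps = as.integer(m_cis),
                       local_multiplier = mult,
                       stringsAsFactors = FALSE),
    esnps = esnps,
    local_threshold = local_threshold,
    alpha = alpha,
    local_method = local_method,
    global_method = global_method),
    class = "hierarchical_result")
}

#' @export
print.hierarchical_result <- function(x, ...) {
  cat(sprintf(
    "hierarchical_result (%s-%s, alpha=%g): %d/%d significant eGenes, %d eSNP calls\n",
    x$local_method, x$global_method, x$alpha, sum(x$genes$significant),
    nrow(x$genes), nrow(x$esnps)))
  invisible(x)
}

#' Pooled multiple-testing correction across all gene-SNP tests
#'
#' Applies one correction method to every record of the association table at
#' once; a gene is called an eGene when at least one of its records is
#' significant at `alpha` after adjustment.
#'
#' @param assoc an `association_table` from [map_cis()].
#' @param method `"st"`, `"bh"`, `"by"` or `"bonferroni"`.
#' @param alpha significance level on the adjusted scale (default 0.05).
#' @return object of class `pooled_result`: `pairs` (significant records with
#'   adjusted p), `egenes` (character vector), `esnps` (per-eGene significant
#'   SNPs, same layout as a hierarchical result's `esnps`), plus tags.
#' @export
pooled_correct <- function(assoc, method = c("bh", "st", "by", "bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (!nrow(assoc)) {
    return(structure(list(
      pairs = data.frame(), egenes = character(0),
      esnps = data.frame(gene_id = character(0), snp_id = character(0),
                         p_local = numeric(0)),
      method = method, alpha = alpha), class = "pooled_result"))
  }
  padj <- adjust_method(assoc$p_nominal, method)
  sig <- which(padj <= alpha)
  pairs <- assoc[sig, c("gene_id", "snp_id", "p_nominal")]
  pairs$p_adjusted <- padj[sig]
  esnps <- data.frame(gene_id = pairs$gene_id, snp_id = pairs$snp_id,
                      p_local = pairs$p_adjusted, stringsAsFactors = FALSE)
  structure(list(pairs = pairs, egenes = unique(pairs$gene_id),
                 esnps = esnps, method = method, alpha = alpha),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("pooled_result (%s, alpha=%g): %d significant pairs, %d eGenes\n",
              x$method, x$alpha, nrow(x$pairs), length(x$egenes)))
  invisible(x)
}

#' Permutation correction for every gene of an association analysis
#'
#' Runs [permutation_local()] per gene over its cis window; the result plugs
#' into [hierarchical_correct()] as the `perm` argument.
#'
#' @param E an [expression_matrix()].
#' @param G a [genotype_matrix()].
#' @param genes gene annotation.
#' @param window cis-window half-width in bp.
#' @inheritParams permutation_local
#' @return named list of per-gene permutation results.
#' @export
permutation_local_all <- function(E, G, genes, window = 1e6,
                                  scheme = "beta", B = 1000L,
                                  B_max = 10000L, seed = 1L) {
  stopifnot(inherits(E, "expression_matrix"), inherits(G, "genotype_matrix"))
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    if (!gid %in% E$gene_ids) next
    idx <- which(G$positions >= genes$tss[i] - window &
                   G$positions <= genes$tss[i] + window)
    if (!length(idx)) next
    sub <- G$dosages[, idx, drop = FALSE]
    keep <- apply(sub, 2, stats::var) > 0
    if (!any(keep)) next
    pr <- permutation_local(E$values[gid, ], sub[, keep, drop = FALSE],
                            scheme = scheme, B = B, B_max = B_max,
                            seed = split_seed(seed, c("perm", gid)))
    pr$p_local <- stats::setNames(pr$p_local, G$snp_ids[idx][keep])
    out[[gid]] <- pr
  }
  out
}
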