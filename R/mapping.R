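#' Precomputed cis-mapping engine
#'
#' Centres the dosage matrix, precomputes per-SNP sums of squares and resolves
#' each gene's cis window once, so that repeated [map_cis()] calls over the
#' same genotypes (e.g. simulation replicates) skip the setup cost.
#'
#' @param G a [genotype_matrix()].
#' @param genes gene annotation (`gene_id`, `tss`).
#' @param window cis-window half-width in bp, inclusive (default 1 Mb).
#' @return object of class `cis_engine`.
#' @export
cis_engine <- function(G, genes, window = 1e6) {
  stopifnot(inherits(G, "genotype_matrix"), is.data.frame(genes), window > 0)
  Xc <- sweep(G$dosages * 1.0, 2, colMeans(G$dosages))
  sxx <- colSums(Xc^2)
  win <- lapply(seq_len(nrow(genes)), function(i) {
    idx <- which(G$positions >= genes$tss[i] - window &
                   G$positions <= genes$tss[i] + window)
    idx[sxx[idx] > 0]
  })
  names(win) <- genes$gene_id
  structure(list(Xc = Xc, sxx = sxx, windows = win, window = window,
                 snp_ids = G$snp_ids, positions = G$positions,
                 n = nrow(G$dosages)),
            class = "cis_engine")
}

#' Map cis-eQTLs by simple linear regression
#'
#' For every gene, fits `y ~ dosage` (with intercept) against each SNP within
#' `window` bp of the gene's TSS (boundary inclusive) and reports the OLS
#' slope, its standard error, the t statistic and the two-sided p-value with
#' `n - 2` degrees of freedom. SNPs with zero dosage variance are skipped.
#' Genes with no in-window SNP contribute no records (a warning names them).
#'
#' @param E an [expression_matrix()]; columns must match `G`'s samples.
#' @param G a [genotype_matrix()].
#' @param genes gene annotation covering `E`'s genes.
#' @param window cis-window half-width in bp (default 1 Mb).
#' @param engine optional precomputed [cis_engine()] for `G`/`genes`.
#' @return an `association_table`: data.frame with columns `gene_id`,
#'   `snp_id`, `beta`, `se`, `t_stat`, `p_nominal`, `distance_to_tss`, rows
#'   grouped by gene; attributes `n_samples` and `window`.
#' @export
map_cis <- function(E, G, genes, window = 1e6, engine = NULL) {
  stopifnot(inherits(E, "expression_matrix"))
  if (is.null(engine)) engine <- cis_engine(G, genes, window)
  ids <- intersect(E$gene_ids, names(engine$windows))
  if (!length(ids)) stop("no genes shared between expression and annotation")
  Y <- E$values
  sn <- colnames(Y)
  gn <- rownames(engine$Xc)
  if (!is.null(sn) && !is.null(gn)) {
    if (!setequal(sn, gn)) stop("no common sample set between E and G")
    Y <- Y[, gn, drop = FALSE]
  } else if (ncol(Y) != engine$n) {
    stop("sample count mismatch between E and G")
  }
  n <- engine$n
  df <- n - 2L
  tss <- stats::setNames(genes$tss, genes$gene_id)
  empty <- character(0)
  res <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    gid <- ids[k]
    idx <- engine$windows[[gid]]
    if (!length(idx)) { empty <- c(empty, gid); next }
    y <- Y[gid, ]
    yc <- y - mean(y)
    syy <- sum(yc^2)
    sxy <- as.vector(crossprod(engine$Xc[, idx, drop = FALSE], yc))
    sxx <- engine$sxx[idx]
    b <- sxy / sxx
    rss <- pmax(syy - b * sxy, 0)
    se <- sqrt(rss / df / sxx)
    t <- ifelse(se > 0, b / se, sign(b) * Inf)
    p <- 2 * stats::pt(-abs(t), df)
    res[[k]] <- list(gene_id = rep(gid, length(idx)),
                     snp_id = engine$snp_ids[idx],
                     beta = b, se = se, t_stat = t,
                     p_nominal = pmax(p, .Machine$double.xmin),
                     distance_to_tss = engine$positions[idx] - tss[[gid]])
  }
  if (length(empty))
    warning(sprintf("%d gene(s) with no in-window SNPs: %s", length(empty),
                    paste(utils::head(empty, 3), collapse = ", ")))
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("no testable gene-SNP pairs")
  out <- data.frame(
    gene_id = unlist(lapply(res, `[[`, "gene_id"), use.names = FALSE),
    snp_id = unlist(lapply(res, `[[`, "snp_id"), use.names = FALSE),
    beta = unlist(lapply(res, `[[`, "beta"), use.names = FALSE),
    se = unlist(lapply(res, `[[`, "se"), use.names = FALSE),
    t_stat = unlist(lapply(res, `[[`, "t_stat"), use.names = FALSE),
    p_nominal = unlist(lapply(res, `[[`, "p_nominal"), use.names = FALSE),
    distance_to_tss = unlist(lapply(res, `[[`, "distance_to_tss"),
                             use.names = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  attr(out, "window") <- engine$window
  class(out) <- c("association_table", "data.frame")
  out
}

# Row indices of each gene's records (list named by gene).
assoc_gene_rows <- function(assoc) {
  split(seq_len(nrow(assoc)), assoc$gene_id)
}

#' Strongest association of a gene
#'
#' Returns the record with the minimum nominal p-value for `gene`; exact ties
#' are broken deterministically in favour of the SNP closest to the start of
#' the chromosome (smallest `distance_to_tss + tss`, i.e. first in genomic
#' order among the tied records).
#'
#' @param assoc an `association_table` from [map_cis()].
#' @param gene gene identifier.
#' @return single-row data.frame.
#' @export
top_association <- function(assoc, gene) {
  rows <- which(assoc$gene_id == gene)
  if (!length(rows)) stop(sprintf("gene '%s' has no association records", gene))
  sub <- assoc[rows, ]
  best <- which(sub$p_nominal == min(sub$p_nominal))
  if (length(best) > 1L)
    best <- best[order(sub$distance_to_tss[best])][1L]
  sub[best, ]
}
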