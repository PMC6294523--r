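#' Effective number of independent tests from the genotype correlation matrix
#'
#' eigenMT-style estimate of the effective number of independent cis SNPs for
#' one gene: SNPs are partitioned into consecutive windows of `window_size`
#' SNPs, each window's dosage correlation matrix is eigendecomposed, the
#' number of leading eigenvalues needed to reach `var_explained` of the total
#' variance is counted, and counts are summed over windows. Used as the
#' multiplier of a local Bonferroni correction in place of the raw SNP count.
#'
#' @param G_cis samples x SNPs dosage matrix of a gene's cis window (or a
#'   [genotype_matrix()], whose dosages are used).
#' @param window_size SNPs per window (default 200).
#' @param var_explained fraction of variance the leading eigenvalues must
#'   reach (default 0.99).
#' @return effective test count `m_eff` with `1 <= m_eff <= ncol(G_cis)`.
#' @export
eigenmt_effective_tests <- function(G_cis, window_size = 200L,
                                    var_explained = 0.99) {
  if (inherits(G_cis, "genotype_matrix")) G_cis <- G_cis$dosages
  G_cis <- as.matrix(G_cis)
  if (!ncol(G_cis)) stop("empty cis genotype matrix")
  v <- apply(G_cis, 2, stats::var)
  G_cis <- G_cis[, v > 0, drop = FALSE]
  if (!ncol(G_cis)) stop("degenerate input: all SNPs are constant")
  m <- ncol(G_cis)
  starts <- seq(1L, m, by = window_size)
  m_eff <- 0L
  for (s in starts) {
    idx <- s:min(s + window_size - 1L, m)
    if (length(idx) == 1L) { m_eff <- m_eff + 1L; next }
    cmat <- stats::cor(G_cis[, idx, drop = FALSE])
    ev <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    k <- which(cumsum(ev) / sum(ev) >= var_explained)[1L]
    m_eff <- m_eff + k
  }
  min(m_eff, m)
}

#' Effective test counts for every gene of an annotation
#'
#' Computes an [eigenmt_effective_tests()]-style `m_eff` per gene cis window.
#' For speed, the SNP windows are anchored at the chromosome start (a fixed
#' tiling into `window_size`-SNP blocks) rather than at each gene's first cis
#' SNP, so the eigendecomposition of every full block is computed once and
#' shared by all genes overlapping it; the partial blocks at a gene's window
#' edges are decomposed exactly on the SNPs present. The result is keyed by
#' gene and reusable across simulation replicates that share the genotype
#' data.
#'
#' @param G a [genotype_matrix()].
#' @param genes gene annotation.
#' @param window cis-window half-width in bp.
#' @inheritParams eigenmt_effective_tests
#' @return named numeric vector of `m_eff` (NA for genes with no cis SNP).
#' @export
eigenmt_all_genes <- function(G, genes, window = 1e6, window_size = 200L,
                              var_explained = 0.99) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosages)
  # unit-norm centered columns: correlations are crossproducts
  X <- G$dosages * 1.0
  X <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(X^2))
  ok <- nrm > 0
  X[, ok] <- sweep(X[, ok, drop = FALSE], 2, nrm[ok], "/")
  count_eigen <- function(idx) {
    idx <- idx[ok[idx]]
    if (!length(idx)) return(0L)
    if (length(idx) == 1L) return(1L)
    cmat <- crossprod(X[, idx, drop = FALSE])
    ev <- pmax(eigen(cmat, symmetric = TRUE, only.values = TRUE)$values, 0)
    which(cumsum(ev) / sum(ev) >= var_explained)[1L]
  }
  block_of <- (seq_len(m) - 1L) %/% window_size
  block_cache <- new.env(parent = emptyenv())
  full_block <- function(b) {
    key <- as.character(b)
    if (is.null(block_cache[[key]]))
      block_cache[[key]] <- count_eigen(which(block_of == b))
    block_cache[[key]]
  }
  out <- stats::setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(genes))) {
    idx <- which(G$positions >= genes$tss[i] - window &
                   G$positions <= genes$tss[i] + window)
    if (!length(idx)) next
    lo <- idx[1]; hi <- idx[length(idx)]
    b_lo <- block_of[lo]; b_hi <- block_of[hi]
    me <- 0L
    for (b in b_lo:b_hi) {
      bidx <- which(block_of == b)
      inside <- bidx[bidx >= lo & bidx <= hi]
      me <- me + if (length(inside) == length(bidx)) full_block(b)
                 else count_eigen(inside)
    }
    out[i] <- min(me, length(idx))
  }
  out
}
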