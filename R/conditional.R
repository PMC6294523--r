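#' Two-stage conditional analysis of independent cis-eQTL signals
#'
#' For each significant eGene of a hierarchical correction, identifies
#' independent eQTL signals at the nominal p-value threshold implied by that
#' correction (the gene's Step-3 local threshold divided by its local
#' multiplier, i.e. the nominal p corresponding to the global FDR 0.05
#' cut-off).
#'
#' **Forward stage** (iterative): starting from the gene's top SNP, cis
#' mapping is repeated conditioning on all accumulated sentinel SNPs
#' (conditioning is implemented by residualising both expression and candidate
#' dosages on the sentinel dosages, with degrees of freedom reduced
#' accordingly — equivalent to including the sentinels as OLS covariates); if
#' the best remaining SNP is still significant it becomes a new sentinel,
#' otherwise the stage stops (at most `max_iter` iterations).
#'
#' **Backward stage:** each sentinel is re-tested in a leave-one-out model
#' conditioning on all other sentinels; only sentinels that remain significant
#' are kept. A sentinel collinear with earlier sentinels is dropped with a
#' warning.
#'
#' @param E an [expression_matrix()].
#' @param G a [genotype_matrix()].
#' @param hier a [hierarchical_correct()] result with Bonferroni-type local
#'   correction (`"bonferroni"` or `"eigenmt"`), which defines the nominal
#'   threshold.
#' @param genes gene annotation.
#' @param window cis-window half-width in bp.
#' @param max_iter forward-stage iteration cap (default 10).
#' @return object of class `independent_signals`: data.frame `signals` with
#'   `gene_id`, `rank`, `snp_id`, `conditional_beta`, `conditional_p`,
#'   `stage_survived`, plus the per-gene `nominal_threshold`s.
#' @export
run_conditional <- function(E, G, hier, genes, window = 1e6, max_iter = 10L) {
  stopifnot(inherits(hier, "hierarchical_result"))
  if (!hier$local_method %in% c("bonferroni", "eigenmt"))
    stop("conditional analysis requires a Bonferroni-type local correction")
  sig <- hier$genes[hier$genes$significant, ]
  if (!nrow(sig)) stop("no significant eGenes to analyse")
  thr_nom <- stats::setNames(hier$local_threshold / sig$local_multiplier,
                             sig$gene_id)
  out <- NULL
  for (gid in sig$gene_id) {
    i <- match(gid, genes$gene_id)
    idx <- which(G$positions >= genes$tss[i] - window &
                   G$positions <= genes$tss[i] + window)
    X <- G$dosages[, idx, drop = FALSE] * 1.0
    keep <- apply(X, 2, stats::var) > 0
    X <- X[, keep, drop = FALSE]
    ids <- G$snp_ids[idx][keep]
    y <- E$values[gid, ]
    thr <- thr_nom[[gid]]

    # forward stage: start from the unconditional top SNP
    p0 <- conditional_scan(y, X, NULL)
    sent <- which.min(p0)
    for (it in seq_len(max_iter)) {
      S <- X[, sent, drop = FALSE]
      if (qr(cbind(1, S))$rank < ncol(S) + 1L) {
        warning(sprintf("%s: dropping collinear sentinel", gid))
        sent <- sent[-length(sent)]
        break
      }
      pc <- conditional_scan(y, X, S)
      pc[sent] <- 1
      best <- which.min(pc)
      if (pc[best] > thr) break
      sent <- c(sent, best)
    }

    # backward stage: leave-one-out re-test
    survived <- logical(length(sent))
    cb <- cp <- numeric(length(sent))
    for (k in seq_along(sent)) {
      others <- if (length(sent) > 1L) X[, sent[-k], drop = FALSE] else NULL
      fit <- conditional_fit(y, X[, sent[k]], others)
      cb[k] <- fit$beta; cp[k] <- fit$p
      survived[k] <- fit$p <= thr
    }
    out <- rbind(out, data.frame(
      gene_id = gid, rank = seq_along(sent), snp_id = ids[sent],
      conditional_beta = cb, conditional_p = cp,
      stage_survived = survived, stringsAsFactors = FALSE))
  }
  structure(list(signals = out[out$stage_survived, , drop = FALSE],
                 all_tested = out, nominal_threshold = thr_nom),
            class = "independent_signals")
}

#' @export
print.independent_signals <- function(x, ...) {
  cat(sprintf("independent_signals: %d signals over %d eGenes\n",
              nrow(x$signals), length(unique(x$signals$gene_id))))
  invisible(x)
}

# Residual-maker: residualise the columns of M on covariates S (with intercept).
residualize <- function(M, S) {
  Q <- qr.Q(qr(cbind(rep(1, nrow(M)), S)))
  M - Q %*% crossprod(Q, M)
}

# p-values of y ~ x_j adjusting for sentinel covariates S (NULL for none).
conditional_scan <- function(y, X, S) {
  n <- length(y)
  k <- if (is.null(S)) 0L else ncol(S)
  df <- n - 2L - k
  R <- residualize(cbind(y, X), S)
  yr <- R[, 1]
  Xr <- R[, -1, drop = FALSE]
  sxx <- colSums(Xr^2)
  syy <- sum(yr^2)
  sxy <- as.vector(crossprod(Xr, yr))
  ok <- sxx > 1e-10 * n
  p <- rep(1, ncol(X))
  b <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - b * sxy[ok], 0)
  tt <- b / sqrt(rss / df / sxx[ok])
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  p
}

# Single conditional fit returning beta and p.
conditional_fit <- function(y, x, S) {
  n <- length(y)
  k <- if (is.null(S)) 0L else ncol(S)
  df <- n - 2L - k
  R <- residualize(cbind(y, x), S)
  yr <- R[, 1]; xr <- R[, 2]
  sxx <- sum(xr^2)
  if (sxx <= 1e-10 * n) return(list(beta = NA_real_, p = 1))
  b <- sum(xr * yr) / sxx
  rss <- max(sum(yr^2) - b * sum(xr * yr), 0)
  tt <- b / sqrt(rss / df / sxx)
  list(beta = b, p = 2 * stats::pt(-abs(tt), df))
}
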