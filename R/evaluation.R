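# Called-eGene/eSNP extraction shared by scorers: named list gene -> snp ids.
called_esnp_sets <- function(calls) {
  es <- calls$esnps
  split(es$snp_id, es$gene_id)
}

# Top SNP (minimum nominal p, genomic-order tie-break) for every gene at once.
top_snps_all <- function(assoc) {
  rows <- assoc_gene_rows(assoc)
  vapply(rows, function(r) {
    p <- assoc$p_nominal[r]
    b <- which(p == min(p))
    if (length(b) > 1L) b <- b[order(assoc$distance_to_tss[r][b])][1L]
    assoc$snp_id[r[b]]
  }, character(1))
}

# TRUE/FALSE per called gene: is it a truth-matched true positive?
match_calls_to_truth <- function(sets, truth, G, ld_threshold = 0.8) {
  causal_by_gene <- split(truth$entries$snp_id, truth$entries$gene_id)
  vapply(names(sets), function(gid) {
    causal <- causal_by_gene[[gid]]
    if (is.null(causal)) return(FALSE)
    snps <- sets[[gid]]
    if (any(causal %in% snps)) return(TRUE)
    idx <- match(snps, G$snp_ids)
    for (cs in causal) {
      r2 <- ld_r2_with(G, match(cs, G$snp_ids), idx)
      if (any(r2 >= ld_threshold)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Score called eGenes against the simulation truth
#'
#' A called eGene is a true positive when it was simulated as a true eGene
#' *and* at least one of its significant eSNPs is in high LD
#' (`r^2 >= ld_threshold`, default 0.8) with one of its simulated causal
#' eSNPs; every other called eGene — including a true eGene detected only
#' through low-LD SNPs — is a false discovery.
#'
#' @param calls a [hierarchical_correct()] or [pooled_correct()] result.
#' @param truth the replicate's [truth_assignments()].
#' @param G the replicate's [genotype_matrix()].
#' @param ld_threshold truth-matching LD threshold (default 0.8).
#' @return list with `tp`, `fp`, `n_called`, `n_true`, `tpr`
#'   (`tp / n_true`) and `fdr` (`fp / n_called`, NA when nothing is called).
#' @export
score_egenes <- function(calls, truth, G, ld_threshold = 0.8) {
  stopifnot(inherits(truth, "truth_assignments"))
  sets <- called_esnp_sets(calls)
  bad <- setdiff(names(sets), all_gene_ids(truth))
  if (length(bad))
    stop(sprintf("called gene(s) absent from truth: %s",
                 paste(utils::head(bad, 3), collapse = ", ")))
  is_tp <- match_calls_to_truth(sets, truth, G, ld_threshold)
  tp <- sum(is_tp)
  n_called <- length(sets)
  n_true <- length(true_egene_ids(truth))
  list(tp = tp, fp = n_called - tp, n_called = n_called, n_true = n_true,
       tpr = tp / n_true,
       fdr = if (n_called) (n_called - tp) / n_called else NA_real_,
       tp_genes = names(sets)[is_tp])
}

#' Score top-eSNP causal identification
#'
#' Among truth-matched (true-positive) eGenes, computes the fraction whose
#' top eSNP (minimum nominal p-value) is the simulated causal eSNP itself or a
#' perfect-LD proxy (`r^2 = 1` up to `perfect_tol`), and — among the top
#' eSNPs that are not — the fraction in high LD (`r^2 >= 0.8`) with the
#' causal eSNP.
#'
#' @param calls a correction result (defines the called eGene set).
#' @param assoc the `association_table` (defines each gene's top eSNP).
#' @inheritParams score_egenes
#' @param perfect_tol slack below 1 still counted as perfect LD (default
#'   1e-9).
#' @return list with `causal_rate`, `highld_rate`, `n_tp`, `n_causal_hit`.
#' @export
score_top_esnp <- function(calls, assoc, truth, G, ld_threshold = 0.8,
                           perfect_tol = 1e-9) {
  sc <- score_egenes(calls, truth, G, ld_threshold)
  tpg <- sc$tp_genes
  if (!length(tpg))
    return(list(causal_rate = NA_real_, highld_rate = NA_real_,
                n_tp = 0L, n_causal_hit = 0L))
  tops <- top_snps_all(assoc)[tpg]
  causal_by_gene <- split(truth$entries$snp_id, truth$entries$gene_id)
  hit <- high <- logical(length(tpg))
  for (k in seq_along(tpg)) {
    causal <- causal_by_gene[[tpg[k]]]
    if (tops[k] %in% causal) { hit[k] <- TRUE; next }
    r2 <- vapply(causal, function(cs)
      ld_r2(G, cs, tops[k]), numeric(1))
    if (max(r2) >= 1 - perfect_tol) hit[k] <- TRUE
    else high[k] <- max(r2) >= ld_threshold
  }
  list(causal_rate = mean(hit),
       highld_rate = if (all(hit)) NA_real_ else mean(high[!hit]),
       n_tp = length(tpg), n_causal_hit = sum(hit))
}

#' Score effect-size estimators against the true effect sizes
#'
#' Error is `estimate - true beta` (overestimation is positive); the median
#' error and mean squared error are reported for the naive and the three
#' bootstrap estimators over the supplied genes (typically the truth-matched
#' true positives, whose causal effect is unambiguous).
#'
#' @param est a [bootstrap_correct()] result.
#' @param truth the replicate's [truth_assignments()] (single-causal).
#' @param genes_subset optional gene ids to restrict to.
#' @return data.frame with one row per estimator: `estimator`,
#'   `median_error`, `mse`, `n`.
#' @export
score_estimators <- function(est, truth, genes_subset = NULL) {
  stopifnot(inherits(est, "bootstrap_estimates"))
  d <- est$estimates
  tb <- stats::setNames(truth$entries$beta, truth$entries$gene_id)
  d <- d[d$gene_id %in% names(tb), ]
  if (!is.null(genes_subset)) d <- d[d$gene_id %in% genes_subset, ]
  cols <- c(naive = "beta_naive", shrinkage = "beta_shrinkage",
            out_of_sample = "beta_oos", weighted = "beta_weighted")
  out <- lapply(names(cols), function(nm) {
    err <- d[[cols[[nm]]]] - tb[d$gene_id]
    data.frame(estimator = nm,
               median_error = if (nrow(d)) stats::median(err) else NA_real_,
               mse = if (nrow(d)) mean(err^2) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scenario configuration
#'
#' Bundles the study conditions of one simulation scenario: sample size,
#' causal-eSNP MAF, effect-size model, genotype-panel geometry and replicate
#' count. Defaults reproduce the package's reference conditions: a 30 Mb
#' synthetic chromosome carrying 26,000 pre-QC SNPs (~15k after QC) and 618
#' genes, 200 of which are true eGenes.
#'
#' @param n_samples study sample size.
#' @param causal_maf target causal-eSNP MAF.
#' @param effects an [effect_dist()].
#' @param coding_mode causal genotype coding.
#' @param noise `"normal"` or `"lognormal"`.
#' @param rank_normalize inverse-rank-normalize expression before mapping.
#' @param n_genes,n_true_egenes gene counts.
#' @param replicates number of simulation replicates.
#' @param n_snps,region_length,n_haplotypes,profile,spectrum panel geometry
#'   (see [simulate_haplotype_panel()]).
#' @param window cis-window half-width in bp.
#' @param maf_tol relative MAF tolerance for causal selection.
#' @param seed master scenario seed; every stage derives its stream from it
#'   via [split_seed()].
#' @param label scenario label used in summaries.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_samples = 500L, causal_maf = 0.1,
                            effects = effect_dist(), coding_mode = "additive",
                            noise = "normal", rank_normalize = FALSE,
                            n_genes = 618L, n_true_egenes = 200L,
                            replicates = 10L, n_snps = 26000L,
                            region_length = 3e7, n_haplotypes = 100L,
                            profile = ld_profile(), spectrum = maf_spectrum(),
                            window = 1e6, maf_tol = 0.2, seed = 1L,
                            label = NULL) {
  stopifnot(n_true_egenes <= n_genes, n_samples >= 1, replicates >= 1,
            causal_maf > 0, causal_maf <= 0.5)
  if (is.null(label))
    label <- sprintf("n%d_maf%g_%s", n_samples, causal_maf,
                     if (effects$family == "constant")
                       sprintf("beta%g", effects$beta) else "gamma")
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate the genotype side of a scenario
#'
#' Builds (once per scenario, reusable across replicates and across scenarios
#' sharing the sample size) the haplotype panel, the QC-filtered genotype
#' matrix, the gene annotation, the cis-mapping engine and, on request, the
#' per-gene effective test counts.
#'
#' @param config a [scenario_config()].
#' @param need_m_eff also compute [eigenmt_all_genes()].
#' @return list with `panel`, `G`, `genes`, `engine`, `m_eff` (or NULL).
#' @export
scenario_genotypes <- function(config, need_m_eff = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  panel <- simulate_haplotype_panel(config$n_haplotypes, config$n_snps,
                                    config$region_length, config$profile,
                                    config$spectrum,
                                    seed = split_seed(config$seed, "panel"))
  G <- sample_genotypes(panel, config$n_samples,
                        seed = split_seed(config$seed, "genotypes"))
  G <- filter_variants(G)
  genes <- simulate_gene_annotation(config$n_genes, config$region_length,
                                    seed = split_seed(config$seed, "genes"))
  engine <- cis_engine(G, genes, config$window)
  m_eff <- if (need_m_eff) eigenmt_all_genes(G, genes, config$window) else NULL
  list(panel = panel, G = G, genes = genes, engine = engine, m_eff = m_eff)
}

parse_method <- function(method) {
  parts <- strsplit(method, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop(sprintf("method '%s' is not 'pooled_<m>' or '<local>_<global>'", method))
  if (parts[1] == "pooled") list(kind = "pooled", method = parts[2])
  else list(kind = "hierarchical", local = parts[1], global = parts[2])
}

apply_method <- function(method, assoc, alpha, m_eff) {
  m <- parse_method(method)
  if (m$kind == "pooled") pooled_correct(assoc, m$method, alpha)
  else hierarchical_correct(assoc, m$local, m$global, alpha, m_eff = m_eff)
}

#' Run one simulation scenario over replicates
#'
#' Per replicate: re-draw the causal-eSNP assignment and effect sizes,
#' simulate expression, map cis-eQTLs, apply every requested correction
#' method, and score eGene calls (and optionally top-eSNP identification and
#' bootstrap effect-size estimators) against the truth. Genotypes are fixed
#' across replicates within the scenario. TPR and FDR are pooled over
#' replicates (total counts, not averaged rates).
#'
#' Methods are named `"pooled_<m>"` (m = `bh`, `st`, `by`, `bonferroni`) or
#' `"<local>_<global>"` (local = `st`, `bh`, `by`, `bonferroni`, `eigenmt`;
#' global = `st`, `bh`, `by`, `bonferroni`), e.g. `"eigenmt_bh"`.
#'
#' @param config a [scenario_config()].
#' @param methods character vector of correction method names.
#' @param alpha significance level (default 0.05).
#' @param shared optional precomputed [scenario_genotypes()] result.
#' @param top_esnp_methods methods for which top-eSNP identification is
#'   scored (default: the hierarchical methods among `methods`).
#' @param bootstrap run [bootstrap_correct()] per replicate (gated by
#'   `bootstrap_gate`, which must be in `methods`).
#' @param bootstrap_gate hierarchical method supplying the significance gate.
#' @param bootstrap_B bootstraps per replicate.
#' @return object of class `scenario_result` with `gene_metrics` (per
#'   method: pooled `tpr`, `fdr`, counts), `top_esnp` (per method), and
#'   `estimators` (pooled error metrics) data.frames, plus `config` and the
#'   per-replicate count table `replicate_counts`.
#' @export
run_scenario <- function(config,
                         methods = c("pooled_bh", "eigenmt_bh",
                                     "bonferroni_bh"),
                         alpha = 0.05, shared = NULL,
                         top_esnp_methods = NULL,
                         bootstrap = FALSE,
                         bootstrap_gate = "bonferroni_bh",
                         bootstrap_B = 200L) {
  stopifnot(inherits(config, "scenario_config"))
  parsed <- lapply(methods, parse_method)
  need_m_eff <- any(vapply(parsed, function(m)
    m$kind == "hierarchical" && m$local == "eigenmt", logical(1)))
  if (is.null(shared)) shared <- scenario_genotypes(config, need_m_eff)
  if (need_m_eff && is.null(shared$m_eff))
    shared$m_eff <- eigenmt_all_genes(shared$G, shared$genes, config$window)
  if (is.null(top_esnp_methods))
    top_esnp_methods <- methods[vapply(parsed, function(m)
      m$kind == "hierarchical", logical(1))]
  if (bootstrap && !bootstrap_gate %in% methods)
    methods <- c(methods, bootstrap_gate)

  counts <- NULL
  top_acc <- list()
  err_acc <- list()
  for (r in seq_len(config$replicates)) {
    rs <- split_seed(config$seed, c("rep", r))
    truth <- select_causal_esnps(
      shared$G, shared$genes, config$causal_maf, config$n_true_egenes,
      maf_tol = config$maf_tol, effects = config$effects,
      coding_mode = config$coding_mode, window = config$window,
      seed = split_seed(rs, "truth"))
    E <- simulate_expression(truth, shared$G, config$noise,
                             seed = split_seed(rs, "expression"))
    if (config$rank_normalize) E <- inverse_rank_normalize(E)
    assoc <- map_cis(E, shared$G, shared$genes, config$window,
                     engine = shared$engine)
    calls_by_method <- list()
    for (mth in methods) {
      calls <- apply_method(mth, assoc, alpha, shared$m_eff)
      calls_by_method[[mth]] <- calls
      sc <- score_egenes(calls, truth, shared$G)
      counts <- rbind(counts, data.frame(
        replicate = r, method = mth, tp = sc$tp, fp = sc$fp,
        n_called = sc$n_called, n_true = sc$n_true,
        stringsAsFactors = FALSE))
      if (mth %in% top_esnp_methods) {
        ts <- score_top_esnp(calls, assoc, truth, shared$G)
        top_acc[[mth]] <- rbind(top_acc[[mth]], data.frame(
          n_tp = ts$n_tp, n_causal_hit = ts$n_causal_hit,
          highld_rate = ts$highld_rate))
      }
    }
    if (bootstrap) {
      gate <- calls_by_method[[bootstrap_gate]]
      if (any(gate$genes$significant)) {
        est <- bootstrap_correct(E, shared$G, gate, assoc,
                                 B_total = bootstrap_B,
                                 seed = split_seed(rs, "bootstrap"))
        sc <- score_egenes(gate, truth, shared$G)
        tb <- stats::setNames(truth$entries$beta, truth$entries$gene_id)
        d <- est$estimates[est$estimates$gene_id %in% sc$tp_genes, ]
        if (nrow(d))
          err_acc[[length(err_acc) + 1L]] <- data.frame(
            replicate = r, gene_id = d$gene_id,
            naive = d$beta_naive - tb[d$gene_id],
            shrinkage = d$beta_shrinkage - tb[d$gene_id],
            out_of_sample = d$beta_oos - tb[d$gene_id],
            weighted = d$beta_weighted - tb[d$gene_id],
            stringsAsFactors = FALSE)
      }
    }
  }

  gene_metrics <- do.call(rbind, lapply(unique(counts$method), function(mth) {
    d <- counts[counts$method == mth, ]
    data.frame(method = mth,
               tpr = sum(d$tp) / sum(d$n_true),
               fdr = if (sum(d$n_called)) sum(d$fp) / sum(d$n_called)
                     else NA_real_,
               mean_significant = mean(d$n_called),
               tp = sum(d$tp), fp = sum(d$fp),
               stringsAsFactors = FALSE)
  }))
  top_esnp <- do.call(rbind, lapply(names(top_acc), function(mth) {
    d <- top_acc[[mth]]
    data.frame(method = mth,
               causal_rate = sum(d$n_causal_hit) / sum(d$n_tp),
               highld_rate = mean(d$highld_rate, na.rm = TRUE),
               n_causal_hit = sum(d$n_causal_hit),
               n_tp = sum(d$n_tp), stringsAsFactors = FALSE)
  }))
  estimators <- NULL
  if (length(err_acc)) {
    errs <- do.call(rbind, err_acc)
    estimators <- do.call(rbind, lapply(
      c("naive", "shrinkage", "out_of_sample", "weighted"), function(nm)
        data.frame(estimator = nm, median_error = stats::median(errs[[nm]]),
                   mse = mean(errs[[nm]]^2), n = nrow(errs),
                   stringsAsFactors = FALSE)))
  }
  structure(list(config = config, gene_metrics = gene_metrics,
                 top_esnp = top_esnp, estimators = estimators,
                 replicate_counts = counts),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result '%s' (%d replicates):\n", x$config$label,
              x$config$replicates))
  print(x$gene_metrics, row.names = FALSE)
  invisible(x)
}

#' Run a grid of scenarios and summarise in long format
#'
#' @param configs list of [scenario_config()]s.
#' @param methods correction methods passed to [run_scenario()].
#' @param ... further arguments passed to [run_scenario()].
#' @return object of class `evaluation_summary`: long data.frame `summary`
#'   (`scenario`, `n_samples`, `causal_maf`, `method`, `metric`, `value`)
#'   plus the full `scenario_result` list.
#' @export
run_scenario_grid <- function(configs, methods = c("pooled_bh", "eigenmt_bh"),
                              ...) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  results <- lapply(configs, run_scenario, methods = methods, ...)
  rows <- list()
  for (res in results) {
    cfg <- res$config
    gm <- res$gene_metrics
    for (i in seq_len(nrow(gm))) {
      for (metric in c("tpr", "fdr", "mean_significant")) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = cfg$label, n_samples = cfg$n_samples,
          causal_maf = cfg$causal_maf, method = gm$method[i],
          metric = metric, value = gm[[metric]][i],
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(res$top_esnp)) for (i in seq_len(nrow(res$top_esnp))) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = cfg$label, n_samples = cfg$n_samples,
        causal_maf = cfg$causal_maf, method = res$top_esnp$method[i],
        metric = "top_esnp_causal_rate",
        value = res$top_esnp$causal_rate[i], stringsAsFactors = FALSE)
    }
    if (!is.null(res$estimators)) for (i in seq_len(nrow(res$estimators))) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = cfg$label, n_samples = cfg$n_samples,
        causal_maf = cfg$causal_maf,
        method = res$estimators$estimator[i],
        metric = "estimator_median_error",
        value = res$estimators$median_error[i], stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), scenarios = results),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation_summary: %d scenarios\n", length(x$scenarios)))
  print(utils::head(x$summary, 20), row.names = FALSE)
  invisible(x)
}

#' Basic power/FDR summary plot
#'
#' Plots pooled TPR and FDR against sample size, one line per correction
#' method, from a [run_scenario_grid()] summary.
#'
#' @param x an `evaluation_summary`.
#' @param metric `"tpr"` or `"fdr"`.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the wide-format matrix plotted.
#' @export
plot_evaluation_summary <- function(x, metric = c("fdr", "tpr"), ...) {
  metric <- match.arg(metric)
  d <- x$summary[x$summary$metric == metric, ]
  wide <- stats::xtabs(value ~ n_samples + method, data = d)
  graphics::matplot(as.numeric(rownames(wide)), wide, type = "b", pch = 16,
                    log = "x", xlab = "sample size", ylab = toupper(metric),
                    lty = 1, ...)
  if (metric == "fdr") graphics::abline(h = 0.05, lty = 2)
  graphics::legend("topleft", legend = colnames(wide), bty = "n",
                   col = seq_len(ncol(wide)), lty = 1, pch = 16)
  invisible(wide)
}
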