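# eqtlpower

Simulation-based evaluation of cis-eQTL study design: statistical power,
gene-level false discovery rate (FDR) calibration of multiple-testing
correction strategies, causal-eSNP identification, and bootstrap correction
of Winner's Curse in effect-size estimation.

## Who this is for

Anyone planning or reviewing a cis-eQTL study — choosing a sample size and
MAF cut-off, deciding between pooled and hierarchical multiple-testing
correction, or interpreting top-eSNP effect sizes — and anyone developing
eQTL methodology who needs LD-realistic synthetic genotype/expression data
with known ground truth.

## What it does

A cis-eQTL scan regresses each gene's expression on the dosage of every SNP
within 1 Mb of the gene's transcription start site,

```
y_i = beta * g_i + e_i,   e_i ~ N(0, 1),   g_i in {0, 1, 2},
```

and must then adjust tens of thousands of p-values per gene set. The package
simulates the whole experiment end to end with known truth:

* **Genotypes** from a self-contained Li–Stephens-style haplotype mosaic:
  founder allele patterns are clades of a random founder genealogy (giving
  realistic perfect- and high-LD proxy structure), expanded into a panel and
  into diploid samples by recombination-mosaic copying; variant QC filters
  on MAF >= 0.5% and HWE p >= 5e-6.
* **Truth**: causal eSNPs drawn at a scenario MAF from an LD-pruned subset
  (pairwise r^2 <= 0.3), one cis gene each; effect sizes constant or
  gamma-distributed; additive, dominant or recessive coding; optional
  multi-causal genes and co-expressed gene blocks.
* **Mapping and correction**: vectorised per-gene OLS; pooled corrections
  (Bonferroni, BH, BY, Storey–Tibshirani q-values) and the hierarchical
  three-step procedure with local corrections including an effective-number-
  of-tests Bonferroni (eigendecomposition of the local genotype correlation
  matrix) and exact / beta-approximated / adaptive permutation schemes.
* **Downstream**: two-stage (forward/backward) conditional analysis of
  independent signals, and bootstrap Winner's-Curse correction with
  shrinkage, out-of-sample and weighted (w = 0.632) estimators.
* **Scoring**: gene-level TPR and FDR against truth (a called eGene counts
  as true only with a significant eSNP at r^2 >= 0.8 to its causal SNP),
  top-eSNP causal identification, and estimator error metrics, pooled over
  replicates.

## Worked example

Forty true eGenes out of 100 genes, causal MAF 10%, effect size 1 s.d. per
allele, 300 samples, three replicates, with the bootstrap effect-size
correction gated by Bonferroni-BH:

```r
library(eqtlpower)
cfg <- scenario_config(
  n_samples = 300, causal_maf = 0.1,
  effects = effect_dist("constant", beta = 1),
  n_genes = 100, n_true_egenes = 40, replicates = 3,
  n_snps = 5000, region_length = 8e6, seed = 1
)
res <- run_scenario(cfg, methods = c("pooled_bh", "eigenmt_bh", "bonferroni_bh"),
                    bootstrap = TRUE, bootstrap_gate = "bonferroni_bh")
res
#> scenario_result 'n300_maf0.1_beta1' (3 replicates):
#>         method       tpr        fdr mean_significant  tp fp
#>      pooled_bh 1.0000000 0.12408759         45.66667 120 17
#>     eigenmt_bh 1.0000000 0.03225806         41.33333 120  4
#>  bonferroni_bh 0.9916667 0.02459016         40.66667 119  3
```

Power is essentially 1 in this easy scenario, but the pooled BH correction
already calls 17 false eGenes (FDR 0.12, over twice the nominal 0.05) while
both hierarchical procedures stay calibrated — the package's central
finding, which grows much more pronounced with sample size.

```r
res$top_esnp
#>          method causal_rate highld_rate n_causal_hit n_tp
#> 1    eigenmt_bh   0.8916667   0.9333333          107  120
#> 2 bonferroni_bh   0.8991597   1.0000000          107  119
```

For ~89% of detected true eGenes the lowest-p SNP is the simulated causal
variant itself (or an exact-LD proxy); almost all the remainder tag it at
r^2 >= 0.8.

```r
res$estimators
#>       estimator  median_error        mse   n
#> 1         naive  1.870773e-02 0.01880899 119
#> 2     shrinkage -1.383343e-02 0.02724027 119
#> 3 out_of_sample -7.277446e-05 0.02214084 119
#> 4      weighted  4.034769e-03 0.02070319 119
```

Errors are estimate minus truth: the naive estimator overestimates (median
error +0.019 even at high power); the bootstrap estimators centre the
median error on zero. In low-power scenarios the naive bias is an order of
magnitude larger and the shrinkage correction matters correspondingly more.

Individual stages (`simulate_haplotype_panel()`, `sample_genotypes()`,
`select_causal_esnps()`, `simulate_expression()`, `map_cis()`,
`hierarchical_correct()`, `pooled_correct()`, `run_conditional()`,
`bootstrap_correct()`, `score_egenes()`) are exported for custom pipelines
and for external genotype (VCF/TSV) and expression (TSV) data; a thin
command-line wrapper lives at `inst/exec/eqtlpower`. The methods vignette
(`vignettes/eqtl-power-simulation.Rmd`) documents the generative models,
defaults and limitations.

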