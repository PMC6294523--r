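---
title: "Simulating cis-eQTL studies: power, FDR calibration and Winner's Curse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cis-eQTL studies: power, FDR calibration and Winner's Curse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cis-eQTL study tests every SNP within 1 Mb of a gene's transcription start
site for association with that gene's expression, across hundreds of genes at
once. Three questions dominate its design: how multiple testing should be
corrected so that the *gene-level* false discovery rate is actually
controlled; how often the most significant SNP of a detected eGene is the
causal variant rather than an LD proxy; and how badly the effect size of a
significant eQTL is overestimated by the very act of selecting it (Winner's
Curse). None of these can be answered from real data alone, because the
truth is unknown there. `eqtlpower` answers them by simulation: it generates
genotypes with realistic linkage disequilibrium, plants known causal eSNPs
with known effect sizes, and scores every analysis strategy against that
truth.

## The generative model

Expression of a true eGene for individual $i$ is

$$y_i = \sum_k \beta_k\, g_{ik} + \varepsilon_i,\qquad \varepsilon_i \sim N(0,1),$$

where $g_{ik} \in \{0,1,2\}$ is the dosage of causal eSNP $k$ (usually one
per gene; optionally two or three, the extras chosen so that their |r| with
the first follows a Beta(2.6, 4.5) distribution). Null genes are pure noise
($\beta = 0$). Dominant and recessive variants recode the dosage as
(0, 2, 2) and (0, 0, 2); a log-normal noise variant (log-mean 0, log-sd 1)
probes the normality assumption, with an inverse rank normal transform
(`qnorm((rank - 0.5)/n)`) available as the standard remedy; and a
co-expression variant gives all true eGenes of a 1 Mb block one shared causal
eSNP plus noise correlated with the block's first gene at
$r_i \sim U(0.6, 0.9)$, via $r_i\varepsilon_1 + \sqrt{1-r_i^2}\,\varepsilon_i$
(unit variance by construction).

Effect sizes are drawn from a gamma distribution with shape 1.8 and scale
0.35 (in s.d. of expression per allele). These values are an explicit
stand-in: the empirical effect-size distribution they imitate comes from a
cohort we do not redistribute, and no published parameters exist; the
defaults give mostly small effects (mean 0.63) with a realistic tail, and
both parameters are configurable. Constant-effect grids
($\beta \in \{0.25, 0.5, 1, 1.5\}$) serve the power analyses.

## The genotype simulator

Reference-quality haplotype data cannot ship with the package, so genotypes
come from a self-contained two-layer mosaic (Li–Stephens-style copying):

1. **Founder patterns from a genealogy.** A fixed random binary tree is
   built over `n_founders` (default 16) founder haplotypes, whose copying
   weights decay geometrically (`0.75^f`, effective founder number ~7). For
   each SNP a target frequency is drawn from a `1/p` spectrum on
   [0.005, 0.5] and the founder allele pattern is the clade of the tree
   whose weight best matches it (Gaussian kernel on log frequency). Nearby
   SNPs of similar frequency therefore often carry the *same* clade
   (perfect LD) or nested clades (high, asymmetric LD) — the structure that
   mutations on a shared genealogy produce in real data. We arrived at this
   design after measuring the plainer alternative (founder alleles i.i.d.
   Bernoulli across founders): it yields essentially no SNP pairs above
   r² = 0.1, which would make every LD-dependent question in the package
   trivially and wrongly easy.
2. **Mosaic expansion.** A 100-haplotype panel copies the founders in
   recombination segments (per-bp switch rate 6e-6, so segments average
   ~170 kb; per-site copy error 1e-3, which also supplies rare variation),
   and each study gamete is in turn a mosaic copy of the panel (copy error
   1e-4). Individuals are sums of two gametes. Because founder assignments
   refresh at every switch, r² decays with distance on the scale of the
   switch rate: with the defaults, mean r² falls from ~0.12 within 10 kb to
   background by ~200 kb, and common SNPs typically have a handful of
   r² ≥ 0.8 proxies within 1 Mb.

Variant QC mirrors standard practice: drop SNPs with folded MAF < 0.5% or
an HWE chi-square (1 df) p below 5e-6. Causal eSNPs are picked at the
scenario MAF (±20% relative tolerance, configurable — no published tolerance
exists) from an LD-pruned subset (pairwise r² ≤ 0.3), each within ±1 Mb of a
distinct gene's TSS.

The default geometry is a 30 Mb synthetic chromosome with 26,000 pre-QC
SNPs (~15k post-QC) and 618 genes, 200 of them true eGenes — a roughly
10-fold scale-down of a chromosome-22-sized study (51 Mb, ~150k post-QC
SNPs, 618 genes) that keeps the gene count and leaves ~1000 SNPs per 2 Mb
cis window. We chose this size so that a 10-replicate scenario runs in a few
minutes on one core; the README's reproduction script uses it unchanged.
One consequence is documented under *Limitations*: effects that scale with
cis SNP density (notably the asymptotic inflation of pooled FDR methods) are
attenuated relative to a full-density chromosome.

What the generator does **not** emulate: population structure and
relatedness, genotyping missingness, multi-chromosome genomes, recombination
hotspots, and the fine-grained site-frequency spectrum of sequencing data.
Tests that pass on these simulations therefore speak to the statistical
machinery under realistic LD, not to robustness against confounding or data
quality problems.

## Mapping and multiple-testing correction

`map_cis()` fits the simple regression `expression ~ dosage` (intercept,
df = n − 2) for every in-window pair, vectorised per gene; the window is
TSS ± 1 Mb inclusive, zero-variance SNPs are skipped, and exact p ties at
the top are broken toward the smaller genomic position.

Corrections come in two shapes:

* **Pooled**: one adjustment across all gene–SNP tests (Bonferroni, BH, BY,
  or Storey–Tibshirani q-values — the latter implemented in-package with the
  λ grid 0.05–0.90 step 0.05, a df-3 smoothing spline evaluated at λ = 0.9,
  and a 1e-3 floor on π₀).
* **Hierarchical (three steps)**: (1) adjust each gene's cis SNPs locally —
  by an FDR method, by Bonferroni with the SNP count, by Bonferroni with the
  eigendecomposition-based *effective* test count, or by permutation;
  (2) take each gene's minimum locally adjusted p and adjust across genes;
  (3) call eSNPs of significant eGenes at the local threshold implied by the
  global 0.05 cut-off — the largest gene-level minimum locally adjusted p
  among significant eGenes, compared inclusively so the boundary eGene keeps
  its own top eSNP.

The effective-test estimate partitions a gene's cis SNPs into 200-SNP
windows, eigendecomposes each window's dosage correlation matrix and counts
the leading eigenvalues reaching 99% of the total variance (both settings
configurable; no canonical values are published, and results are insensitive
within reason). In `eigenmt_all_genes()` the windows are anchored at the
chromosome start so that each full window's decomposition is shared by all
overlapping genes; only the partial windows at a gene's edges are
recomputed. This makes the estimate reusable across replicates, which is
also statistically right: it depends only on genotypes, which are fixed
within a scenario.

Permutation local correction shuffles expression labels, keeps the minimum
nominal p per permutation, and converts the observed minimum via
`(r+1)/(B+1)` (exact), a maximum-likelihood beta fit to the permuted minima
(beta approximation, moment-matching start, 1e-6 parameter floor), or the
beta fit after adaptive batching (batches of 100 until 15 exceedances or
10,000 permutations). The spec'd tests confirm the beta scheme at B = 1000
rank-correlates > 0.99 with the exact scheme at B = 10,000.

## Conditional analysis and bootstrap Winner's-Curse correction

For each significant eGene, the two-stage conditional analysis runs a
forward pass (iteratively re-scan the cis window conditioning on accumulated
sentinels — implemented by residualising expression and candidate dosages on
the sentinel dosages with df reduced accordingly; at most 10 iterations as a
safety valve) and a backward pass (leave-one-out re-test of every sentinel).
The significance threshold is the nominal p corresponding to the
hierarchical global 0.05 cut-off. Comparisons are inclusive (≤) for the
boundary reason above.

The bootstrap correction draws, per bootstrap, an n-out-of-n resample
(detection group) and its out-of-bag complement (estimation group; ~36.8% of
samples). Each significant eGene's top eSNP — fixed from the original
analysis, never re-discovered — is re-estimated in both groups; the
bootstrap counts toward the gene's $B_e$ only if the detection-group nominal
p times the gene's original local multiplier beats the original Step-3
threshold. The three estimators are the shrinkage estimator
$\hat\beta_N - \frac{1}{B_e}\sum_i(\hat\beta_{Di} - \hat\beta_{Ei})$, the
out-of-sample estimator $\frac{1}{B_e}\sum_i \hat\beta_{Ei}$, and the
weighted estimator $(1-\omega)\hat\beta_N + \omega\,\overline{\hat\beta_E}$
with $\omega = 0.632$, the expected unique-sample fraction of the resample
($1-(1-1/n)^n \to 1 - 1/e$). Genes never re-detected keep the naive estimate
and are flagged rather than silently corrected. Per-bootstrap RNG streams
are keyed by `(seed, bootstrap index)`, so results do not depend on
evaluation order.

## Scoring against truth

A called eGene is a true positive only if it was simulated as a true eGene
*and* one of its significant eSNPs has r² ≥ 0.8 with its causal eSNP; a true
eGene detected only through low-LD SNPs counts as a false discovery. TPR and
FDR pool counts over replicates (not averages of per-replicate rates), and a
scenario with zero calls reports FDR as missing. Top-eSNP identification
counts the causal SNP itself or an exact-LD proxy (r² = 1 within 1e-9) as a
hit; effect-size error is estimate − truth (overestimation positive),
summarised by median and MSE over truth-matched eGenes.

## Numerical and design choices

* **Randomness**: one master seed per scenario; every stage (panel,
  genotypes, per-replicate truth, expression, permutations, bootstraps)
  derives its own stream via `split_seed()`, a 31-bit mix of seed and a
  string key, so stages are reproducible in isolation and under
  parallelisation.
* **Truth per replicate**: causal SNP assignments and effect sizes are
  re-drawn every replicate while genotypes stay fixed within a scenario —
  pooled metrics then average over the SNP-selection randomness as well as
  the noise.
* **Dosage polarity**: dosages count the simulated (ALT) allele and `maf` is
  the folded frequency, keeping VCF round trips lossless when an allele
  drifts above 50% in a finite sample; association statistics and r² are
  flip-invariant.
* **Degenerate inputs**: monomorphic SNPs are filtered (or skipped by the
  mapper), constant expression is a hard error for permutation and rank
  normalisation, empty estimation groups skip a bootstrap with a warning,
  collinear sentinels are dropped with a warning.
* **Boundary conventions**: cis windows are inclusive; Step-3 and
  conditional thresholds are inclusive; permutation p has the `(r+1)/(B+1)`
  floor.

## Problem sizes used by the tests and the reproduction script

The replicated scenarios run at the default geometry with 10 replicates:
n = 1000 / MAF 25% / gamma effects (FDR calibration), n = 2000 / MAF 50% /
gamma (pooled inflation), n = 200 / MAF 5% / β = 1.5 (power), and
n = 1000 / MAF 5% / β = 1 plus n = 500 / MAF 25% / β = 1.5 (top-eSNP
identification). The Winner's-Curse scenario uses a reduced 10 Mb / 8000-SNP
/ 150-gene geometry at n = 200 so that 10 replicates × 200 bootstraps stay
inexpensive. These sizes are the package's reference conditions; all of them
complete on one core in a few minutes each.

## Known limitations

* Pooled-FDR inflation grows with cis SNP density, so its desk-scale
  asymptote (~0.5 at n = 2000, MAF 50%) sits below what a full-density
  chromosome shows (> 0.6); the direction and ordering of all methods are
  unaffected.
* The top-eSNP identification rate is LD-profile dependent; we quote it with
  a ±10-point band around the ~90% reference value.
* The mosaic generator's LD is blocky and stationary along the chromosome;
  it does not reproduce recombination hotspots or long-range admixture LD.
* Trans-eQTLs, covariates, count-based expression models and population
  structure are out of scope.
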