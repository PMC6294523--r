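#include <Rcpp.h>
using namespace Rcpp;

// Mosaic-copy `n_copies` haplotypes from a template panel.
// templates: haplotypes x SNPs 0/1 integer matrix; p_switch: per-SNP
// probability that a new template is drawn before this SNP (first entry
// must be 1); weights: cumulative donor weights (empty = uniform).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".copy_mosaic_many")]]
IntegerMatrix copy_mosaic_many(const IntegerMatrix& templates,
                               const NumericVector& p_switch,
                               double mutation_rate,
                               const NumericVector& cum_weights,
                               int n_copies) {
  const int s = p_switch.size();
  const int n_templates = templates.nrow();
  const bool weighted = cum_weights.size() > 0;
  IntegerMatrix out(n_copies, s);
  for (int h = 0; h < n_copies; ++h) {
    int donor = 0;
    for (int j = 0; j < s; ++j) {
      if (unif_rand() < p_switch[j]) {
        if (weighted) {
          double u = unif_rand();
          int lo = 0, hi = n_templates - 1;
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (cum_weights[mid] < u) lo = mid + 1; else hi = mid;
          }
          donor = lo;
        } else {
          donor = (int)(unif_rand() * n_templates);
          if (donor == n_templates) donor = n_templates - 1;
        }
      }
      int a = templates(donor, j);
      if (mutation_rate > 0 && unif_rand() < mutation_rate) a = 1 - a;
      out(h, j) = a;
    }
  }
  return out;
}

// Genotype count tabulation per SNP: returns 3 x SNPs counts of dosages
// 0/1/2 (used by the HWE filter without allocating logical matrices).
// [[Rcpp::export(name = ".dosage_counts")]]
IntegerMatrix dosage_counts(const IntegerMatrix& dosages) {
  const int n = dosages.nrow(), m = dosages.ncol();
  IntegerMatrix out(3, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      out(dosages(i, j), j)++;
  return out;
}
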