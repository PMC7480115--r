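#include <Rcpp.h>
using namespace Rcpp;

// Pooled null G-scores for one chromosome.
//
// altered: m x s 0/1 matrix (sample altered at marker, chosen direction)
// contrib: m x s matrix of |log2| * altered (amplitude contributions)
// offsets: n_perm x s matrix of circular shifts in [0, m)
// n_tumor: frequency denominator (total tumors, not just these columns)
//
// Returns a numeric vector of length m * n_perm: for every permutation,
// each sample's marker profile is rotated by its offset and the track is
// rescored as G = (altered/n_tumor) * (sum|log2| / altered).
// [[Rcpp::export]]
NumericVector perm_null_chrom(IntegerMatrix altered, NumericMatrix contrib,
                              IntegerMatrix offsets, int n_tumor) {
  const int m = altered.nrow();
  const int s = altered.ncol();
  const int n_perm = offsets.nrow();
  NumericVector out(static_cast<R_xlen_t>(m) * n_perm);
  std::vector<int> a_sum(m);
  std::vector<double> v_sum(m);

  for (int p = 0; p < n_perm; ++p) {
    std::fill(a_sum.begin(), a_sum.end(), 0);
    std::fill(v_sum.begin(), v_sum.end(), 0.0);
    for (int j = 0; j < s; ++j) {
      const int off = offsets(p, j) % m;
      const int *a = &altered(0, j);
      const double *v = &contrib(0, j);
      // marker i of the shifted profile reads position (i + off) mod m
      int idx = off;
      for (int i = 0; i < m; ++i) {
        a_sum[i] += a[idx];
        v_sum[i] += v[idx];
        if (++idx == m) idx = 0;
      }
    }
    double *o = &out[static_cast<R_xlen_t>(p) * m];
    for (int i = 0; i < m; ++i) {
      o[i] = a_sum[i] > 0
        ? (static_cast<double>(a_sum[i]) / n_tumor) * (v_sum[i] / a_sum[i])
        : 0.0;
    }
  }
  return out;
}
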