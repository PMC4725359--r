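#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of the values of row `t` of `mat` at 1-based column indices idx
static double row_median_at(const NumericMatrix& mat, int t,
                            const IntegerMatrix& idx, int rep,
                            std::vector<double>& buf) {
  const int k = idx.nrow();
  buf.resize(k);
  for (int j = 0; j < k; ++j) buf[j] = mat(t, idx(j, rep) - 1);
  std::sort(buf.begin(), buf.end());
  if (k % 2 == 1) return buf[k / 2];
  return 0.5 * (buf[k / 2 - 1] + buf[k / 2]);
}

// two-sided Wilcoxon rank-sum p-value, normal approximation with average
// ranks, tie-corrected variance and continuity correction (the large-sample
// path of R's wilcox.test). Returns NA when the variance is zero (all
// values tied across both groups).
static double ranksum_p_normal(const std::vector<double>& a,
                               const std::vector<double>& b) {
  const int n1 = (int)a.size(), n2 = (int)b.size(), n = n1 + n2;
  std::vector<std::pair<double, int> > v(n);
  for (int i = 0; i < n1; ++i) v[i] = std::make_pair(a[i], 0);
  for (int i = 0; i < n2; ++i) v[n1 + i] = std::make_pair(b[i], 1);
  std::sort(v.begin(), v.end());
  double wsum = 0.0;       // rank sum of group a
  double tiecorr = 0.0;    // sum over tie groups of t^3 - t
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[j].first == v[i].first) ++j;
    const double avg = 0.5 * (i + 1 + j);  // average of ranks i+1 .. j
    const double t = j - i;
    if (t > 1) tiecorr += t * t * t - t;
    for (int k = i; k < j; ++k)
      if (v[k].second == 0) wsum += avg;
    i = j;
  }
  const double u = wsum - n1 * (n1 + 1.0) / 2.0;  // Mann-Whitney U
  double z = u - n1 * (double)n2 / 2.0;
  const double var = (n1 * (double)n2 / 12.0) *
      ((n + 1.0) - tiecorr / ((double)n * (n - 1.0)));
  if (var <= 0) return NA_REAL;
  const double cc = (z > 0) ? 0.5 : (z < 0 ? -0.5 : 0.0);
  z = (z - cc) / std::sqrt(var);
  double p = 2.0 * std::min(R::pnorm(z, 0.0, 1.0, 1, 0),
                            R::pnorm(z, 0.0, 1.0, 0, 0));
  return std::min(1.0, p);
}

//' @noRd
// [[Rcpp::export(name = ".boot_iteration_pvalues")]]
NumericVector boot_iteration_pvalues(NumericMatrix mat,
                                     IntegerMatrix idx_a,
                                     IntegerMatrix idx_b) {
  const int n_taxa = mat.nrow();
  const int reps = idx_a.ncol();
  if (idx_b.ncol() != reps)
    stop("index matrices must have the same number of repetitions");
  NumericVector p(n_taxa);
  std::vector<double> buf, med_a(reps), med_b(reps);
  for (int t = 0; t < n_taxa; ++t) {
    for (int r = 0; r < reps; ++r) {
      med_a[r] = row_median_at(mat, t, idx_a, r, buf);
      med_b[r] = row_median_at(mat, t, idx_b, r, buf);
    }
    p[t] = ranksum_p_normal(med_a, med_b);
  }
  return p;
}
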