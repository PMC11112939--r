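#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation primitives.
//
// The split statistic for an arc [i, j) of a length-n segment is the
// scaled mean difference between the arc and its (circular) complement:
//   T(i,j) = |mean(arc) - mean(rest)| / sqrt(1/k + 1/(n-k)),  k = j - i.
// The noise SD is constant across permutations of the same data, so it is
// dropped from the statistic; permutation p-values are unaffected.

static double best_arc(const std::vector<double> &cs, int n, int min_seg,
                       int *bi, int *bj) {
  const double total = cs[n];
  double best = -1.0;
  if (bi) *bi = -1;
  if (bj) *bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i;
      const int rest = n - k;
      if (k < min_seg || rest < min_seg) continue;
      const double s = cs[j] - cs[i];
      const double diff = s / k - (total - s) / rest;
      const double stat = std::fabs(diff) / std::sqrt(1.0 / k + 1.0 / rest);
      if (stat > best) {
        best = stat;
        if (bi) *bi = i;
        if (bj) *bj = j;
      }
    }
  }
  return best;
}

static void prefix_sums(const std::vector<double> &x, std::vector<double> &cs) {
  const int n = (int)x.size();
  cs.resize(n + 1);
  cs[0] = 0.0;
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
}

// Find the best arc split of x and assess it by permutation.
//
// Permutations consume R's RNG stream (seed with set.seed() upstream).
// Early stopping: once the exceedance count guarantees the full-nperm
// p-value (exceed + 1) / (nperm + 1) >= alpha the split is rejected
// without running the remaining permutations; the accept/reject decision
// is identical to running all nperm permutations.
// [[Rcpp::export(name = ".cbs_find_split")]]
List cbs_find_split(NumericVector x, double alpha, int nperm, int min_seg) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> cs;
  prefix_sums(v, cs);

  int bi, bj;
  const double obs = best_arc(cs, n, min_seg, &bi, &bj);
  if (bi < 0 || !(obs > 0.0))
    return List::create(_["accept"] = false, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER, _["p_value"] = 1.0,
                        _["stat"] = obs, _["n_perm_done"] = 0);

  const double cut = alpha * (nperm + 1.0);
  int exceed = 0, done = 0;
  std::vector<double> y(v);
  for (int p = 0; p < nperm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    prefix_sums(y, cs);
    if (best_arc(cs, n, min_seg, NULL, NULL) >= obs) ++exceed;
    done = p + 1;
    if (exceed + 1 >= cut) break;
  }
  const double pval = (exceed + 1.0) / (done + 1.0);
  // Early stop only happens when the split is already doomed, so a run that
  // completes all nperm permutations is the only way to accept.
  const bool ok = (done == nperm) && ((exceed + 1.0) / (nperm + 1.0)) < alpha;
  return List::create(_["accept"] = ok, _["i"] = bi, _["j"] = bj,
                      _["p_value"] = pval, _["stat"] = obs,
                      _["n_perm_done"] = done);
}

// Exhaustive best single/double change-point statistics, used by the
// segmentation only through cbs_find_split; exported for reuse in
// diagnostics (tests keep their own independent R oracle).
// [[Rcpp::export(name = ".cbs_max_stat")]]
double cbs_max_stat(NumericVector x, int min_seg) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> cs;
  prefix_sums(v, cs);
  return best_arc(cs, n, min_seg, NULL, NULL);
}
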