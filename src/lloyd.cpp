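#include <Rcpp.h>
using namespace Rcpp;

// Lloyd iterations for k-means with fixed initial centers.
// Ties in the assignment step go to the lowest cluster index; empty clusters
// retain their previous center. Both rules keep the fit deterministic for a
// given initialization. Iteration stops when assignments are stable or the
// relative WCSS improvement drops below tol.
// [[Rcpp::export]]
List lloyd_cpp(const NumericMatrix& x, const NumericMatrix& init,
               const int maxIter, const double tol = 1e-8) {
  const int n = x.nrow(), d = x.ncol(), k = init.nrow();
  std::vector<double> cen(init.begin(), init.end());   // column-major k x d
  std::vector<double> sums((size_t)k * d, 0.0);
  std::vector<int> cnt(k, 0);
  IntegerVector lab(n, 0);
  int iter = 0;
  bool changed = true;
  double prevObj = R_PosInf;

  while (changed && iter < maxIter) {
    changed = false;
    ++iter;
    double obj = 0.0;  // WCSS under the centers of the previous update
    std::fill(sums.begin(), sums.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = x(i, c) - cen[j + (size_t)c * k];
          s += diff * diff;
          if (s >= best) break;  // cannot beat current best (strict <)
        }
        if (s < best) { best = s; bj = j; }
      }
      obj += best;
      if (lab[i] != bj + 1) { lab[i] = bj + 1; changed = true; }
      cnt[bj]++;
      for (int c = 0; c < d; ++c) sums[bj + (size_t)c * k] += x(i, c);
    }
    if (changed) {
      for (int j = 0; j < k; ++j) {
        if (cnt[j] > 0)
          for (int c = 0; c < d; ++c)
            cen[j + (size_t)c * k] = sums[j + (size_t)c * k] / cnt[j];
      }
    }
    if (prevObj - obj <= tol * prevObj) break;  // diminishing returns
    prevObj = obj;
  }

  // Centers as means of the final assignment (no-op when converged), then
  // the within-cluster sum of squares under that assignment.
  std::fill(sums.begin(), sums.end(), 0.0);
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int i = 0; i < n; ++i) {
    const int j = lab[i] - 1;
    cnt[j]++;
    for (int c = 0; c < d; ++c) sums[j + (size_t)c * k] += x(i, c);
  }
  for (int j = 0; j < k; ++j)
    if (cnt[j] > 0)
      for (int c = 0; c < d; ++c)
        cen[j + (size_t)c * k] = sums[j + (size_t)c * k] / cnt[j];

  double wcss = 0.0;
  for (int i = 0; i < n; ++i) {
    const int j = lab[i] - 1;
    for (int c = 0; c < d; ++c) {
      const double diff = x(i, c) - cen[j + (size_t)c * k];
      wcss += diff * diff;
    }
  }

  NumericMatrix centers(k, d);
  std::copy(cen.begin(), cen.end(), centers.begin());
  return List::create(_["labels"] = lab, _["centers"] = centers,
                      _["wcss"] = wcss, _["iterations"] = iter);
}
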