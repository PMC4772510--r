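#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive GINI-gain split search over the candidate columns of X.
// y must be 0/1. Candidate thresholds are the midpoints between consecutive
// distinct sorted values of each column (for a 0/1 fingerprint column this
// reduces to the single threshold 0.5). Ties in gain are broken by the
// lowest column index, then the lowest threshold, which the scan order
// guarantees. Returns feature = 0 when no admissible split has
// gain > min_gain.
// [[Rcpp::export]]
List rf_best_split_cpp(NumericMatrix X, IntegerVector y, double min_gain,
                       int min_samples_leaf) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2)
    return List::create(_["feature"] = 0, _["threshold"] = NA_REAL,
                        _["gain"] = NA_REAL);
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[i];
  const int n0 = n - n1;
  const double parent =
      1.0 - ((double)n0 * n0 + (double)n1 * n1) / ((double)n * n);

  double best_gain = -1.0, best_thr = 0.0;
  int best_col = -1;
  std::vector<int> idx(n);

  for (int c = 0; c < p; ++c) {
    NumericMatrix::Column col = X(_, c);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    int cum1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      cum1 += y[idx[i]];
      const double xi = col[idx[i]], xj = col[idx[i + 1]];
      if (!(xj > xi)) continue;  // no distinct-value boundary here
      const int nl = i + 1, nr = n - nl;
      if (nl < min_samples_leaf || nr < min_samples_leaf) continue;
      const int l1 = cum1, l0 = nl - l1, r1 = n1 - l1, r0 = nr - r1;
      const double gl =
          1.0 - ((double)l0 * l0 + (double)l1 * l1) / ((double)nl * nl);
      const double gr =
          1.0 - ((double)r0 * r0 + (double)r1 * r1) / ((double)nr * nr);
      const double gain = parent - (nl * gl + nr * gr) / n;
      if (gain > best_gain + 1e-15) {
        double thr = 0.5 * (xi + xj);
        // with adjacent doubles the midpoint can round onto xj, which would
        // send every row left under the "<= threshold" rule; clamp to xi so
        // the partition realized matches the one whose gain was scored
        if (!(thr > xi && thr < xj)) thr = xi;
        best_gain = gain;
        best_col = c;
        best_thr = thr;
      }
    }
  }
  if (best_col < 0 || !(best_gain > min_gain))
    return List::create(_["feature"] = 0, _["threshold"] = NA_REAL,
                        _["gain"] = NA_REAL);
  return List::create(_["feature"] = best_col + 1, _["threshold"] = best_thr,
                      _["gain"] = best_gain);
}

// Root-to-leaf traversal of a flat node store for every row of X.
// feature is 1-based (0 marks a leaf); left/right are 1-based node ids.
// Rule: go left iff x[feature] <= threshold.
// [[Rcpp::export]]
IntegerVector rf_predict_tree_cpp(IntegerVector feature,
                                  NumericVector threshold, IntegerVector left,
                                  IntegerVector right, IntegerVector label,
                                  NumericMatrix X, int root) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = root - 1;
    while (feature[node] > 0) {
      const double v = X(i, feature[node] - 1);
      node = (v <= threshold[node]) ? left[node] - 1 : right[node] - 1;
    }
    out[i] = label[node];
  }
  return out;
}
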