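#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive axis-aligned split search for a two-class node.
//
// For every column of X the candidate thresholds are the midpoints between
// consecutive distinct sorted values; the split sends value <= threshold to
// the left child.  The returned split maximises the weighted Gini decrease
//   G(parent) - nL/n * G(left) - nR/n * G(right).
// Ties are broken towards the lowest column index, then the smallest
// threshold (guaranteed by strict ">" comparisons while scanning columns and
// thresholds in ascending order).  col == 0 signals "no split".
//
// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, IntegerVector y, int min_split_size) {
  const int n = X.nrow(), p = X.ncol();
  List none = List::create(_["col"] = 0, _["threshold"] = NA_REAL,
                           _["decrease"] = 0.0);
  if (n < min_split_size || n < 2) return none;

  int tot1 = 0;
  for (int i = 0; i < n; ++i) tot1 += y[i];
  const int tot0 = n - tot1;
  if (tot1 == 0 || tot0 == 0) return none;  // pure node

  const double p1 = (double)tot1 / n, p0 = (double)tot0 / n;
  const double gini_parent = 1.0 - p1 * p1 - p0 * p0;

  int best_col = 0;
  double best_thr = NA_REAL, best_dec = 0.0;
  const double eps = 1e-12;

  std::vector<int> idx(n);
  for (int j = 0; j < p; ++j) {
    NumericMatrix::Column xj = X.column(j);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return xj[a] < xj[b]; });
    int n1L = 0;  // binders routed left so far
    for (int k = 0; k < n - 1; ++k) {
      n1L += y[idx[k]];
      const double v = xj[idx[k]], vnext = xj[idx[k + 1]];
      if (v == vnext) continue;  // not a boundary between distinct values
      const int nL = k + 1, nR = n - nL;
      const int n1R = tot1 - n1L;
      const double pl1 = (double)n1L / nL, pl0 = 1.0 - pl1;
      const double pr1 = (double)n1R / nR, pr0 = 1.0 - pr1;
      const double gl = 1.0 - pl1 * pl1 - pl0 * pl0;
      const double gr = 1.0 - pr1 * pr1 - pr0 * pr0;
      const double dec =
          gini_parent - ((double)nL / n) * gl - ((double)nR / n) * gr;
      if (dec > best_dec + eps) {
        best_dec = dec;
        best_col = j + 1;
        best_thr = v + (vnext - v) / 2.0;
      }
    }
  }
  if (best_col == 0 || best_dec <= eps) return none;
  return List::create(_["col"] = best_col, _["threshold"] = best_thr,
                      _["decrease"] = best_dec);
}
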