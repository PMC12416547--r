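#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Row-wise midranks and rank-sum tie corrections for a dense matrix.
// Returns the rank matrix (average ranks within ties) and, per row, the
// tie correction term sum(t^3 - t) over tied groups, as used by the
// normal approximation of the Wilcoxon rank-sum test.
// [[Rcpp::export(rng = false)]]
List row_rank_stats(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix ranks(nr, nc);
  NumericVector tie(nr);
  std::vector<int> idx(nc);
  std::vector<double> row(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      idx[j] = j;
      row[j] = x(i, j);
    }
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return row[a] < row[b]; });
    double tcorr = 0.0;
    int j = 0;
    while (j < nc) {
      int k = j;
      while (k + 1 < nc && row[idx[k + 1]] == row[idx[j]]) ++k;
      const double avg = (j + k) / 2.0 + 1.0;
      const double t = k - j + 1;
      for (int m = j; m <= k; ++m) ranks(i, idx[m]) = avg;
      if (t > 1) tcorr += t * t * t - t;
      j = k + 1;
    }
    tie[i] = tcorr;
  }
  return List::create(_["ranks"] = ranks, _["tie"] = tie);
}
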