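#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming accumulation over a cost matrix:
// D(i,j) = min(D(i-1,j-1), D(i-1,j), D(i,j-1)) + C(i,j), D(1,1) = C(1,1),
// out-of-range predecessors treated as +Inf.
// [[Rcpp::export]]
NumericMatrix dtw_accumulate_cpp(NumericMatrix cost) {
  int n = cost.nrow(), m = cost.ncol();
  NumericMatrix D(n, m);
  D(0, 0) = cost(0, 0);
  for (int j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + cost(0, j);
  for (int i = 1; i < n; ++i) {
    D(i, 0) = D(i - 1, 0) + cost(i, 0);
    for (int j = 1; j < m; ++j) {
      double d = D(i - 1, j - 1);
      if (D(i - 1, j) < d) d = D(i - 1, j);
      if (D(i, j - 1) < d) d = D(i, j - 1);
      D(i, j) = d + cost(i, j);
    }
  }
  return D;
}

// Backtrack the optimal warping path from the terminal cell. Ties are
// broken diagonal > vertical (i-1,j) > horizontal (i,j-1), which yields
// the shortest path among equal-cost alternatives. Returns an l x 2
// matrix of 1-based (i, j) pairs from (1,1) to (n,m).
// [[Rcpp::export]]
IntegerMatrix dtw_backtrack_cpp(NumericMatrix D) {
  int n = D.nrow(), m = D.ncol();
  std::vector<std::pair<int, int> > rev;
  int i = n - 1, j = m - 1;
  rev.push_back(std::make_pair(i, j));
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    rev.push_back(std::make_pair(i, j));
  }
  int l = rev.size();
  IntegerMatrix path(l, 2);
  for (int k = 0; k < l; ++k) {
    path(k, 0) = rev[l - 1 - k].first + 1;
    path(k, 1) = rev[l - 1 - k].second + 1;
  }
  return path;
}
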