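#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local cost: squared Euclidean distance between sample i of a and j of b.
static inline double sqdist(const NumericMatrix &a, int i,
                            const NumericMatrix &b, int j) {
  double dx = a(i, 0) - b(j, 0);
  double dy = a(i, 1) - b(j, 1);
  return dx * dx + dy * dy;
}

// Accumulated DTW cost with unit-weight steps {(1,0),(0,1),(1,1)} and full
// boundary alignment; O(min(m,n)) memory, no path.
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericMatrix a, NumericMatrix b) {
  const int m = a.nrow(), n = b.nrow();
  std::vector<double> prev(n), cur(n);
  prev[0] = sqdist(a, 0, b, 0);
  for (int j = 1; j < n; ++j) prev[j] = prev[j - 1] + sqdist(a, 0, b, j);
  for (int i = 1; i < m; ++i) {
    cur[0] = prev[0] + sqdist(a, i, b, 0);
    for (int j = 1; j < n; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = best + sqdist(a, i, b, j);
    }
    std::swap(prev, cur);
  }
  return prev[n - 1];
}

// Full DP with backtracking. Ties broken in favor of the diagonal step, then
// the vertical one. Returns the accumulated cost and the warping path as a
// (path length) x 2 matrix of 1-based (i, j) index pairs.
// [[Rcpp::export(name = ".dtw_path_cpp")]]
List dtw_path_cpp(NumericMatrix a, NumericMatrix b) {
  const int m = a.nrow(), n = b.nrow();
  NumericMatrix D(m, n);
  // step codes: 1 = diag, 2 = up (i-1), 3 = left (j-1), 0 = origin
  IntegerMatrix S(m, n);
  D(0, 0) = sqdist(a, 0, b, 0);
  S(0, 0) = 0;
  for (int j = 1; j < n; ++j) { D(0, j) = D(0, j - 1) + sqdist(a, 0, b, j); S(0, j) = 3; }
  for (int i = 1; i < m; ++i) { D(i, 0) = D(i - 1, 0) + sqdist(a, i, b, 0); S(i, 0) = 2; }
  for (int i = 1; i < m; ++i) {
    for (int j = 1; j < n; ++j) {
      double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
      int s = 1; double best = diag;
      if (up < best) { best = up; s = 2; }
      if (left < best) { best = left; s = 3; }
      D(i, j) = best + sqdist(a, i, b, j);
      S(i, j) = s;
    }
  }
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  while (true) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    int s = S(i, j);
    if (s == 0) break;
    if (s == 1) { --i; --j; }
    else if (s == 2) { --i; }
    else { --j; }
  }
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["cost"] = D(m - 1, n - 1), _["path"] = path);
}
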