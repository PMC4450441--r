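#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input: logical/integer matrix (non-zero =
// foreground). Output: integer matrix with the 1-px-wide skeleton.
// Border pixels are treated as background (they never thin incorrectly
// because the neighbourhood test requires all 8 neighbours).
// [[Rcpp::export(name = ".thin_zhang_suen")]]
IntegerMatrix thin_zhang_suen(const IntegerMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix cur(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      cur(i, j) = img(i, j) != 0 ? 1 : 0;

  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!cur(i, j)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = cur(i - 1, j),     p3 = cur(i - 1, j + 1);
          int p4 = cur(i, j + 1),     p5 = cur(i + 1, j + 1);
          int p6 = cur(i + 1, j),     p7 = cur(i + 1, j - 1);
          int p8 = cur(i, j - 1),     p9 = cur(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        cur(kill[k].first, kill[k].second) = 0;
    }
  }
  return cur;
}

// Min-cost assignment (Hungarian algorithm with potentials) on a square
// cost matrix. Returns the 1-based column assigned to each row.
// [[Rcpp::export(name = ".hungarian_square")]]
IntegerVector hungarian_square(const NumericMatrix& cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n != m) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double curc = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (curc < minv[j]) { minv[j] = curc; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
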