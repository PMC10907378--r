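#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Dense linear assignment by shortest augmenting paths with dual potentials
// (Jonker-Volgenant family). Deterministic: columns are scanned in index
// order, so ties are broken by the smallest column index.
// cost must be square; entries may be R_PosInf (forbidden). Forbidden entries
// are replaced internally by a large finite value so a complete matching
// always exists; callers must check which matched pairs were admissible.
// [[Rcpp::export]]
List lap_solve_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return List::create(_["assignment"] = IntegerVector(0),
                                  _["cost"] = 0.0);

  // finite stand-in for forbidden entries
  double maxfin = 0.0;
  for (int i = 0; i < n * n; ++i) {
    double v = cost[i];
    if (R_finite(v) && std::abs(v) > maxfin) maxfin = std::abs(v);
  }
  const double BIG = (maxfin + 1.0) * n * 4.0 + 1.0;

  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  const double INF = std::numeric_limits<double>::infinity();

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cij = cost(i0 - 1, j - 1);
        if (!R_finite(cij)) cij = BIG;
        double cur = cij - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector assignment(n);
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    assignment[p[j] - 1] = j;  // 1-based column for row p[j]
    double cij = cost(p[j] - 1, j - 1);
    total += R_finite(cij) ? cij : R_PosInf;
  }
  return List::create(_["assignment"] = assignment, _["cost"] = total);
}
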