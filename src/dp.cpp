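#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Elastic reparameterization by dynamic programming on the m x m lattice.
//
// Nodes (i, j) identify grid points (t_i, s_j) of the matching function
// gamma with gamma(t_i) = s_j. Allowed steps (di, dj) have di, dj in 1..K,
// gcd(di, dj) == 1 (duplicate slopes removed), so local slopes range over
// [1/K, K]. The cost of an edge is the trapezoidal quadrature of
// |q1(t) - sqrt(gamma') q2(gamma(t))|^2 over the segment, with gamma linear
// on the segment and q2 linearly interpolated. Ties prefer diagonal-like
// steps (transitions are scanned in order of |di - dj| and strict
// improvement is required to replace the incumbent).

static int gcd_int(int a, int b) { return b == 0 ? a : gcd_int(b, a % b); }

static double edge_cost(const NumericMatrix &q1, const NumericMatrix &q2,
                        int i0, int i1, int j0, int j1, int m) {
  const double h = 1.0 / (m - 1);
  const double slope = static_cast<double>(j1 - j0) / (i1 - i0);
  const double sq = std::sqrt(slope);
  double total = 0.0;
  for (int p = i0; p <= i1; ++p) {
    double g = (j0 + slope * (p - i0)) * h;      // gamma(t_p) in [0,1]
    double x = g * (m - 1);
    int k = static_cast<int>(std::floor(x));
    if (k >= m - 1) k = m - 2;
    double frac = x - k;
    double f = 0.0;
    for (int d = 0; d < 3; ++d) {
      double q2g = (1.0 - frac) * q2(k, d) + frac * q2(k + 1, d);
      double diff = q1(p, d) - sq * q2g;
      f += diff * diff;
    }
    double w = (p == i0 || p == i1) ? 0.5 : 1.0;
    total += w * f;
  }
  return total * h;
}

// [[Rcpp::export]]
List dp_reparam_cpp(NumericMatrix q1, NumericMatrix q2, int K) {
  const int m = q1.nrow();
  if (q2.nrow() != m) stop("grid sizes differ");
  if (m < 3) stop("grid too small for dynamic programming (need >= 3)");
  if (K < 1) stop("K must be >= 1");

  std::vector<std::pair<int, int>> steps;
  for (int di = 1; di <= K; ++di)
    for (int dj = 1; dj <= K; ++dj)
      if (gcd_int(di, dj) == 1) steps.push_back(std::make_pair(di, dj));
  std::stable_sort(steps.begin(), steps.end(),
                   [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                     int da = std::abs(a.first - a.second);
                     int db = std::abs(b.first - b.second);
                     if (da != db) return da < db;
                     return a.first + a.second < b.first + b.second;
                   });

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> E(static_cast<size_t>(m) * m, INF);
  std::vector<int> Pi(static_cast<size_t>(m) * m, -1), Pj(static_cast<size_t>(m) * m, -1);
  E[0] = 0.0;

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i == 0 && j == 0) continue;
      double best = INF;
      int bi = -1, bj = -1;
      for (size_t s = 0; s < steps.size(); ++s) {
        int i0 = i - steps[s].first, j0 = j - steps[s].second;
        if (i0 < 0 || j0 < 0) continue;
        double e0 = E[static_cast<size_t>(i0) * m + j0];
        if (!std::isfinite(e0)) continue;
        double c = e0 + edge_cost(q1, q2, i0, i, j0, j, m);
        if (c < best) { best = c; bi = i0; bj = j0; }
      }
      E[static_cast<size_t>(i) * m + j] = best;
      Pi[static_cast<size_t>(i) * m + j] = bi;
      Pj[static_cast<size_t>(i) * m + j] = bj;
    }
  }

  double cost = E[static_cast<size_t>(m - 1) * m + (m - 1)];
  if (!std::isfinite(cost)) stop("no admissible lattice path (increase K)");

  // backtrack, then express gamma at every grid index by linear segments
  std::vector<int> path_i, path_j;
  int ci = m - 1, cj = m - 1;
  while (ci >= 0 && cj >= 0) {
    path_i.push_back(ci); path_j.push_back(cj);
    if (ci == 0 && cj == 0) break;
    int ni = Pi[static_cast<size_t>(ci) * m + cj];
    int nj = Pj[static_cast<size_t>(ci) * m + cj];
    ci = ni; cj = nj;
  }

  NumericVector gamma(m);
  const double h = 1.0 / (m - 1);
  for (size_t s = path_i.size() - 1; s > 0; --s) {
    int i0 = path_i[s], j0 = path_j[s];
    int i1 = path_i[s - 1], j1 = path_j[s - 1];
    double slope = static_cast<double>(j1 - j0) / (i1 - i0);
    for (int p = i0; p <= i1; ++p)
      gamma[p] = (j0 + slope * (p - i0)) * h;
  }
  gamma[0] = 0.0;
  gamma[m - 1] = 1.0;

  return List::create(_["gamma"] = gamma, _["cost"] = cost);
}

// Exposed so tests can price a single lattice edge with the exact
// arithmetic the DP uses.
// [[Rcpp::export]]
double dp_edge_cost_cpp(NumericMatrix q1, NumericMatrix q2,
                        int i0, int i1, int j0, int j1) {
  const int m = q1.nrow();
  if (q2.nrow() != m) stop("grid sizes differ");
  if (i1 <= i0 || j1 <= j0) stop("edge must move forward in both indices");
  return edge_cost(q1, q2, i0, i1, j0, j1, m);
}
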