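#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shortest open Hamiltonian path by Held-Karp dynamic programming over
// vertex subsets. The free choice of start vertex (dp[{j}][j] = 0) is the
// dummy-node formulation: a zero-cost vertex closes the path into a tour.
// O(n^2 * 2^n) time, O(n * 2^n) memory; n is capped to keep memory sane.
// [[Rcpp::export(name = ".held_karp_path")]]
List held_karp_path(NumericMatrix d) {
  const int n = d.nrow();
  if (n != d.ncol()) stop("distance matrix must be square");
  if (n < 1) stop("empty distance matrix");
  if (n > 20) stop("exact solver limited to n <= 20 (got %d)", n);
  if (n == 1)
    return List::create(_["order"] = IntegerVector::create(1),
                        _["length"] = 0.0);

  const size_t nstates = (size_t)1 << n;
  std::vector<double> dp(nstates * n, R_PosInf);
  std::vector<int> par(nstates * n, -1);
  for (int j = 0; j < n; ++j) dp[(((size_t)1 << j)) * n + j] = 0.0;

  for (size_t mask = 1; mask < nstates; ++mask) {
    for (int j = 0; j < n; ++j) {
      if (!((mask >> j) & 1)) continue;
      const double cur = dp[mask * n + j];
      if (!R_FINITE(cur)) continue;
      for (int k = 0; k < n; ++k) {
        if ((mask >> k) & 1) continue;
        const size_t nm = mask | ((size_t)1 << k);
        const double cand = cur + d(j, k);
        if (cand < dp[nm * n + k]) {
          dp[nm * n + k] = cand;
          par[nm * n + k] = j;
        }
      }
    }
  }

  const size_t full = nstates - 1;
  int best = 0;
  double bestlen = dp[full * n + 0];
  for (int j = 1; j < n; ++j)
    if (dp[full * n + j] < bestlen) { bestlen = dp[full * n + j]; best = j; }

  IntegerVector path(n);
  size_t mask = full;
  int j = best;
  for (int i = n - 1; i >= 0; --i) {
    path[i] = j + 1;
    const int p = par[mask * n + j];
    mask ^= (size_t)1 << j;
    j = p;
  }
  return List::create(_["order"] = path, _["length"] = bestlen);
}

static double path_length(const NumericMatrix& d, const std::vector<int>& p) {
  double len = 0.0;
  for (size_t i = 1; i < p.size(); ++i) len += d(p[i - 1], p[i]);
  return len;
}

// Nearest-neighbour construction from each requested start (ties broken by
// lowest vertex index), refined by first-improvement 2-opt for the open
// path; returns the best refined path and the best plain-NN length.
// [[Rcpp::export(name = ".nn_two_opt")]]
List nn_two_opt(NumericMatrix d, IntegerVector starts) {
  const int n = d.nrow();
  if (n != d.ncol()) stop("distance matrix must be square");
  std::vector<int> best;
  double bestlen = R_PosInf, best_nn = R_PosInf;

  for (int si = 0; si < starts.size(); ++si) {
    const int s = starts[si] - 1;
    if (s < 0 || s >= n) stop("start index out of range");
    std::vector<int> p;
    p.reserve(n);
    std::vector<bool> used(n, false);
    int cur = s;
    p.push_back(cur);
    used[cur] = true;
    for (int step = 1; step < n; ++step) {
      int nxt = -1;
      double bd = R_PosInf;
      for (int k = 0; k < n; ++k)
        if (!used[k] && d(cur, k) < bd) { bd = d(cur, k); nxt = k; }
      p.push_back(nxt);
      used[nxt] = true;
      cur = nxt;
    }
    const double nnlen = path_length(d, p);
    if (nnlen < best_nn) best_nn = nnlen;

    // 2-opt: reverse p[i..j]; for an open path only the boundary edges
    // (i-1,i) and (j,j+1) change, absent when the segment touches an end.
    double len = nnlen;
    bool improved = true;
    while (improved) {
      improved = false;
      for (int i = 0; i < n - 1; ++i) {
        for (int jj = i + 1; jj < n; ++jj) {
          if (i == 0 && jj == n - 1) continue;  // whole-path reversal: no-op
          double delta = 0.0;
          if (i > 0) delta += d(p[i - 1], p[jj]) - d(p[i - 1], p[i]);
          if (jj < n - 1) delta += d(p[i], p[jj + 1]) - d(p[jj], p[jj + 1]);
          if (delta < -1e-12) {
            std::reverse(p.begin() + i, p.begin() + jj + 1);
            len += delta;
            improved = true;
          }
        }
      }
    }
    len = path_length(d, p);  // re-accumulate to shed float drift
    if (len < bestlen) { bestlen = len; best = p; }
  }

  IntegerVector ord(n);
  for (int i = 0; i < n; ++i) ord[i] = best[i] + 1;
  return List::create(_["order"] = ord, _["length"] = bestlen,
                      _["nn_length"] = best_nn);
}
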