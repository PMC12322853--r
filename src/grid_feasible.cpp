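#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive reference check for MACBETH judgment feasibility.
//
// Enumerates every assignment of integer values 0..gmax to the n items
// (with pruning) and, for each, asks whether strictly increasing integer
// thresholds t_1 < ... < t_6 (t_1 >= 1, spacing >= 1) exist that place
// each judged difference in its category band:
//   code k >= 1:  t_k <= v_i - v_j  and, for k <= 5,  v_i - v_j <= t_{k+1} - 1
//   code 0:       v_i == v_j
// Threshold existence given fixed values is decided greedily: take each
// t_k as small as its lower bounds allow and check it against the smallest
// difference of category k. This is exact because every constraint on t_k
// is either a lower bound or the single upper bound min-diff(k).
//
// Deliberately independent of the simplex path used by the package: used
// as the brute-force oracle in tests.

static bool thresholds_exist(const int *dmin, const int *dmax,
                             const bool *present) {
  int t_prev = 0;
  for (int k = 1; k <= 6; ++k) {
    int lb = t_prev + 1;
    if (k >= 2 && present[k - 1] && dmax[k - 1] + 1 > lb)
      lb = dmax[k - 1] + 1;
    if (present[k] && lb > dmin[k]) return false;
    t_prev = lb;
  }
  return true;
}

// [[Rcpp::export(name = ".grid_feasible_cpp")]]
bool grid_feasible_cpp(int n, IntegerVector pi, IntegerVector pj,
                       IntegerVector code, int gmax) {
  int np = pi.size();
  std::vector<int> v(n, 0);
  // pairs_at[d]: judgments whose later-assigned endpoint is item d
  std::vector<std::vector<int> > pairs_at(n);
  for (int c = 0; c < np; ++c) {
    int later = std::max(pi[c], pj[c]);
    pairs_at[later].push_back(c);
  }

  int depth = 0;
  v[0] = 0;
  while (depth >= 0) {
    bool ok = true;
    // incremental necessary checks for pairs completed at this depth
    for (size_t q = 0; ok && q < pairs_at[depth].size(); ++q) {
      int c = pairs_at[depth][q];
      int d = v[pi[c]] - v[pj[c]];
      if (code[c] == 0) {
        if (d != 0) ok = false;
      } else {
        // minimal thresholds are t_k >= k, so d >= code is necessary
        if (d < code[c]) ok = false;
      }
    }
    if (ok && depth == n - 1) {
      int dmin[7], dmax[7];
      bool present[7];
      for (int k = 0; k <= 6; ++k) present[k] = false;
      for (int c = 0; c < np; ++c) {
        int k = code[c];
        if (k == 0) continue;
        int d = v[pi[c]] - v[pj[c]];
        if (!present[k]) { dmin[k] = dmax[k] = d; present[k] = true; }
        else {
          if (d < dmin[k]) dmin[k] = d;
          if (d > dmax[k]) dmax[k] = d;
        }
      }
      if (thresholds_exist(dmin, dmax, present)) return true;
      ok = false;  // leaf exhausted; advance
    }
    if (ok) {
      ++depth;
      v[depth] = 0;
      continue;
    }
    // advance: increment v[depth], backtracking on overflow
    while (depth >= 0) {
      if (v[depth] < gmax) { ++v[depth]; break; }
      --depth;
    }
  }
  return false;
}
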