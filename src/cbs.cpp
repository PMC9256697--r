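// Circular binary segmentation kernel.
//
// For a stretch of n window values, the candidate split is the arc (i, j]
// maximizing the two-sample t-statistic between the arc and its
// complement. With the value multiset fixed (as it is across
// permutations), the total sum of squares is constant, so maximizing |t|
// is equivalent to maximizing the between-group sum of squares
//   B(i,j) = (S~[j] - S~[i])^2 * n / (m * (n - m)),  m = j - i,
// where S~ are mean-centered partial sums. The permutation test therefore
// compares max-B between the observed ordering and seeded shuffles.
//
// The permutation scan only needs to know whether a shuffle's max-B
// reaches the observed value. Arc lengths are grouped in dyadic blocks;
// for each block a sliding-window range bound on the centered partial
// sums decides in O(n) whether any arc of that length range can reach the
// threshold, and only unpruned blocks are scanned exactly. The decision is
// identical to the full scan; the bound is conservative.

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// arc (i, j], 2 <= m <= n-2; flanks, when non-empty, must keep >= 2
// windows so every resulting segment has the minimum width
static inline bool arc_ok(int i, int j, int n) {
  if (i > 0 && i < 2) return false;
  if (j < n && j > n - 2) return false;
  return true;
}

static void centered_prefix(const std::vector<double>& x,
                            std::vector<double>& S) {
  int n = x.size();
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i] - mu;
}

// [[Rcpp::export(name = ".cbs_best_arc")]]
List cbs_best_arc(NumericVector xr) {
  int n = xr.size();
  if (n < 4) return List::create(_["i"] = 0, _["j"] = 0, _["B"] = 0.0);
  std::vector<double> x(xr.begin(), xr.end());
  std::vector<double> S(n + 1);
  centered_prefix(x, S);
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int m = 2; m <= n - 2; ++m) {
    const double w = (double)n / ((double)m * (double)(n - m));
    for (int i = 0; i + m <= n; ++i) {
      int j = i + m;
      if (!arc_ok(i, j, n)) continue;
      double d = S[j] - S[i];
      double b = d * d * w;
      if (b > best) { best = b; bi = i; bj = j; }
    }
  }
  return List::create(_["i"] = bi, _["j"] = bj, _["B"] = best);
}

// does this shuffle's max-B reach Bstar?
static bool shuffle_exceeds(const std::vector<double>& S, int n,
                            double Bstar,
                            std::vector<double>& wmax,
                            std::vector<double>& wmin) {
  for (int M = 2; M <= n - 2; M *= 2) {
    int Mhi = std::min(2 * M - 1, n - 2);
    // sliding range of S over windows of length L = Mhi + 1 (block trick)
    int L = Mhi + 1;
    int len = n + 1;             // S has n+1 entries
    if (L > len) L = len;
    // prefix/suffix extrema within blocks of size L
    for (int i = 0; i < len; ++i) {
      if (i % L == 0) { wmax[i] = S[i]; wmin[i] = S[i]; }
      else {
        wmax[i] = std::max(wmax[i - 1], S[i]);
        wmin[i] = std::min(wmin[i - 1], S[i]);
      }
    }
    std::vector<double>& smax = wmax; // forward pass stored in wmax/wmin
    // suffix pass stored separately
    static thread_local std::vector<double> sufmax, sufmin;
    sufmax.assign(len, 0.0); sufmin.assign(len, 0.0);
    for (int i = len - 1; i >= 0; --i) {
      if (i == len - 1 || (i + 1) % L == 0) {
        sufmax[i] = S[i]; sufmin[i] = S[i];
      } else {
        sufmax[i] = std::max(sufmax[i + 1], S[i]);
        sufmin[i] = std::min(sufmin[i + 1], S[i]);
      }
    }
    double bound = 0.0;
    for (int t = 0; t + L <= len; ++t) {
      double mx = std::max(sufmax[t], smax[t + L - 1]);
      double mn = std::min(sufmin[t], wmin[t + L - 1]);
      double r = mx - mn;
      if (r > bound) bound = r;
    }
    double minmn = std::min((double)M * (n - M), (double)Mhi * (n - Mhi));
    double thr2_level = Bstar * minmn / n;
    if (bound * bound < thr2_level) continue; // no arc in block can reach
    for (int m = M; m <= Mhi; ++m) {
      double thr2 = Bstar * (double)m * (double)(n - m) / n;
      for (int i = 0; i + m <= n; ++i) {
        int j = i + m;
        if (!arc_ok(i, j, n)) continue;
        double d = S[j] - S[i];
        if (d * d >= thr2) return true;
      }
    }
  }
  return false;
}

// [[Rcpp::export(name = ".cbs_perm_test")]]
List cbs_perm_test(NumericVector xr, double Bstar, int nperm,
                   int stop_exceed, int seed) {
  int n = xr.size();
  std::vector<double> x(xr.begin(), xr.end());
  std::vector<double> S(n + 1), wmax(n + 1), wmin(n + 1);
  std::mt19937 rng((uint32_t)seed);
  int exceed = 0, done = 0;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> U(0, i);
      int k = U(rng);
      std::swap(x[i], x[k]);
    }
    centered_prefix(x, S);
    if (shuffle_exceeds(S, n, Bstar, wmax, wmin)) ++exceed;
    ++done;
    if (exceed >= stop_exceed) break; // decision fixed: not significant
  }
  return List::create(_["exceed"] = exceed, _["nperm_done"] = done);
}
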