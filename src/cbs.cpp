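#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal standardized circular arc statistic for one segment.
// Arcs that wrap around the circle have the same |Z| as their complement,
// so scanning non-wrapping arcs (i, j] with 0 <= i < j <= n, j - i < n
// covers the circular family. Both the arc and its complement must have at
// least min_width probes. Returns -1 when no admissible arc exists.
static double max_arc_stat(const std::vector<double> &x, int min_width,
                           int *bi, int *bj) {
  const int n = (int)x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double total = S[n];
  const double mean = total / n;
  double ss = 0.0;
  for (int t = 0; t < n; ++t) ss += (x[t] - mean) * (x[t] - mean);
  double s2 = (n > 1) ? ss / (n - 1) : 0.0;
  if (s2 <= 0.0) s2 = 1e-300;  // constant segment: all Z become 0
  double best = -1.0;
  *bi = -1; *bj = -1;
  for (int i = 0; i <= n - min_width; ++i) {
    for (int j = i + min_width; j <= n; ++j) {
      const int k = j - i;
      if (n - k < min_width) continue;
      const double arc = S[j] - S[i];
      const double mean_in = arc / k;
      const double mean_out = (total - arc) / (n - k);
      const double z = (mean_in - mean_out) /
                       std::sqrt(s2 * (1.0 / k + 1.0 / (n - k)));
      const double az = std::fabs(z);
      if (az > best) { best = az; *bi = i; *bj = j; }
    }
  }
  return best;
}

// Test one segment for a change-point: observed max arc statistic plus a
// permutation P-value with early termination once significance at `alpha`
// is no longer attainable. Uses R's RNG, so results follow set.seed().
// [[Rcpp::export]]
List cbs_test_segment(NumericVector x_, int min_width, int nperm,
                      double alpha) {
  std::vector<double> x = as<std::vector<double> >(x_);
  const int n = (int)x.size();
  int bi, bj;
  const double obs = max_arc_stat(x, min_width, &bi, &bj);
  if (obs < 0.0 || n < 2 * min_width)
    return List::create(_["significant"] = false, _["stat"] = NA_REAL,
                        _["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["p"] = NA_REAL, _["n_perm_used"] = 0);
  const double stop_at = alpha * (nperm + 1);  // (1+count) >= stop_at => p >= alpha
  int count = 0, done = 0;
  std::vector<double> xp(x);
  bool early = false;
  for (int b = 0; b < nperm; ++b) {
    for (int t = n - 1; t > 0; --t) {  // Fisher-Yates with R uniforms
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(xp[t], xp[u]);
    }
    int pi, pj;
    const double st = max_arc_stat(xp, min_width, &pi, &pj);
    ++done;
    if (st >= obs) {
      ++count;
      if (1.0 + count >= stop_at) { early = true; break; }
    }
  }
  double p;
  bool significant;
  if (early) {
    p = (1.0 + count) / (done + 1.0);  // lower bound; already >= alpha
    significant = false;
  } else {
    p = (1.0 + count) / (nperm + 1.0);
    significant = p < alpha;
  }
  return List::create(_["significant"] = significant, _["stat"] = obs,
                      _["i"] = bi, _["j"] = bj, _["p"] = p,
                      _["n_perm_used"] = done);
}
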