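#include <Rcpp.h>
using namespace Rcpp;

// Exact penalized piecewise-constant fit.
//
// Minimizes  sum over segments of within-segment SSE  +  penalty * (#segments - 1)
// subject to every segment containing at least kmin points. Ties are broken
// toward fewer segments, then toward the earliest last breakpoint.
//
// Returns 1-based segment start indices.
// [[Rcpp::export(name = ".dp_segment")]]
IntegerVector dp_segment(NumericVector x, double penalty, int kmin) {
  int n = x.size();
  if (n == 0) return IntegerVector(0);
  if (kmin < 1) kmin = 1;
  if (n < 2 * kmin) {
    IntegerVector out(1); out[0] = 1; return out;
  }
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    css[i + 1] = css[i] + x[i] * x[i];
  }
  // sse of x[i..j-1] (0-based, half-open)
  auto sse = [&](int i, int j) {
    double s = cs[j] - cs[i];
    return (css[j] - css[i]) - s * s / (j - i);
  };
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> best(n + 1, INF);
  std::vector<int> nseg(n + 1, 0), prev(n + 1, -1);
  best[0] = 0.0;
  for (int j = kmin; j <= n; ++j) {
    // last segment is x[i..j-1]; i == 0 starts the sequence (no penalty)
    for (int i = 0; i + kmin <= j; ++i) {
      if (i > 0 && (i < kmin || !std::isfinite(best[i]))) continue;
      double cand = best[i] + sse(i, j) + (i > 0 ? penalty : 0.0);
      int cand_nseg = nseg[i] + 1;
      bool take = false;
      if (cand < best[j]) take = true;
      else if (cand == best[j]) {
        if (cand_nseg < nseg[j]) take = true;
        else if (cand_nseg == nseg[j] && (prev[j] < 0 || i < prev[j])) take = true;
      }
      if (take) { best[j] = cand; nseg[j] = cand_nseg; prev[j] = i; }
    }
  }
  std::vector<int> starts;
  int j = n;
  while (j > 0) { starts.push_back(prev[j] + 1); j = prev[j]; }
  std::reverse(starts.begin(), starts.end());
  return wrap(starts);
}
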