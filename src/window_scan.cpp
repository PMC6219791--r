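// Core sliding-window scan for one chromosome.
//
// Reads at sorted positions pos[0..n-1] define B = n-1 bins; bin i (1-based)
// lies between reads i and i+1.  An initial window starting at bin j spans
// bins j..min(j+w-1, B) (trailing windows at the chromosome end keep their
// actual, shorter span).  Its step windows are anchored at the 3' end e:
// step k keeps bins (e-k+1)..e, k = 1..span.  A step window containing any
// bin of length >= max_allowed is excluded.  Each surviving step window of
// k bins holds R_case = k+1 reads over l = pos[e+1]-pos[s] bp and is scored
// by the upper Poisson tail P(X >= R_case) with
//   lambda = max(d_genome * l, R_control * sf)            (control present)
//   lambda = d_genome * l                                  (no control)
// (l floored at 1 bp so lambda > 0 even for duplicate-read windows).
// The minimum-p step window is the final window of the initial window;
// ties prefer the longer (then 5'-most) window.

#include <Rcpp.h>
using namespace Rcpp;

// ctrl_le[i]: number of control reads with position <= pos[i] - 1, and
// ctrl_le_at[i]: number <= pos[i]; both length n, computed in R via
// findInterval so the count over [pos[s], pos[e+1]] inclusive is
// ctrl_le_at[e+1] - ctrl_le[s].

// [[Rcpp::export]]
List scan_final_windows(IntegerVector pos, int w, double max_allowed,
                        double dgenome, double sf,
                        IntegerVector ctrl_le_at, IntegerVector ctrl_le,
                        bool use_ctrl) {
  const int n = pos.size();
  const int B = n - 1;
  if (B < 1 || w < 1)
    return List::create(_["s"] = IntegerVector(0), _["e"] = IntegerVector(0),
                        _["p"] = NumericVector(0));

  // bad[e] (1-based): largest bin index <= e whose length >= max_allowed
  std::vector<int> bad(B + 1, 0);
  for (int e = 1; e <= B; ++e) {
    double len = (double)pos[e] - pos[e - 1];
    bad[e] = (len >= max_allowed) ? e : bad[e - 1];
  }

  std::vector<int> out_s, out_e;
  std::vector<double> out_p;
  out_s.reserve(B); out_e.reserve(B); out_p.reserve(B);

  for (int j = 1; j <= B; ++j) {
    int e = std::min(j + w - 1, B);
    int span = e - j + 1;
    int kmax = std::min(span, e - bad[e]);
    if (kmax <= 0) continue;
    double best_p = R_PosInf;
    int best_k = -1;
    double full_lambda = 1.0;  // lambda of the widest step (k = kmax)
    for (int k = 1; k <= kmax; ++k) {
      int s = e - k + 1;  // window = bins s..e, reads pos[s-1]..pos[e] (0-based)
      double l = (double)pos[e] - pos[s - 1];
      if (l < 1.0) l = 1.0;
      double lambda = dgenome * l;
      if (use_ctrl) {
        double rc = (double)ctrl_le_at[e] - ctrl_le[s - 1];
        double lc = rc * sf;
        if (lc > lambda) lambda = lc;
      }
      if (k == kmax) full_lambda = lambda;
      // R_case = k + 1.  When R_case <= lambda the tail P(X >= R_case) is
      // at least ~0.37, so the window can never pass any corrected-p
      // threshold below 0.05 and cannot displace an enriched competitor;
      // skip the expensive tail evaluation.
      if ((double)(k + 1) <= lambda) continue;
      double p = R::ppois((double)k, lambda, 0, 0);  // P(X > k) = P(X >= k+1)
      // <= : on ties the later (larger k, i.e. longer, 5'-most) window wins
      if (p <= best_p) { best_p = p; best_k = k; }
    }
    if (best_k < 0) {
      // every step was at or below expectation: record the full-span step
      // (insignificant by construction) so the window count is preserved
      best_k = kmax;
      best_p = R::ppois((double)kmax, full_lambda, 0, 0);
    }
    out_s.push_back(e - best_k + 1);
    out_e.push_back(e);
    out_p.push_back(best_p);
  }
  return List::create(_["s"] = wrap(out_s), _["e"] = wrap(out_e),
                      _["p"] = wrap(out_p));
}

// Fragment pileup summit: reads (shifted positions) are extended by
// `shift` on both sides; the summit is the leftmost position of maximum
// pileup within [rstart, rend).  Interval ends are clipped to the region.

// [[Rcpp::export]]
List pileup_summit(IntegerVector pos, int shift, int rstart, int rend) {
  const int n = pos.size();
  if (n == 0)
    return List::create(_["summit"] = NA_INTEGER, _["height"] = 0);
  std::vector<std::pair<int, int> > ev;  // (coordinate, +1/-1)
  ev.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    int a = pos[i] - shift, b = pos[i] + shift + 1;  // [a, b) covered
    if (b <= rstart || a >= rend) continue;
    ev.push_back(std::make_pair(std::max(a, rstart), +1));
    ev.push_back(std::make_pair(std::min(b, rend), -1));
  }
  if (ev.empty())
    return List::create(_["summit"] = NA_INTEGER, _["height"] = 0);
  std::sort(ev.begin(), ev.end());
  int cur = 0, best = -1, summit = rstart;
  for (size_t i = 0; i < ev.size();) {
    int x = ev[i].first;
    while (i < ev.size() && ev[i].first == x) { cur += ev[i].second; ++i; }
    if (cur > best && x < rend) { best = cur; summit = x; }
  }
  return List::create(_["summit"] = summit, _["height"] = best);
}
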