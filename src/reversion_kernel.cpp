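#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Running-sum extremum of the weighted KS statistic for one drug and one
// gene set, evaluated at hit boundaries only.  Mirrors the R reference
// implementation exactly: candidates are visited in path order and on
// exact ties of the absolute extremum the earliest one wins.
static double es_one(const IntegerMatrix& ranks, const NumericMatrix& absz,
                     int d, const IntegerVector& idx, int G) {
  const int m = idx.size();
  if (m == 0) return 0.0;
  std::vector<std::pair<int, double> > h(m);
  for (int i = 0; i < m; ++i) {
    const int g = idx[i] - 1;  // 1-based gene column index
    h[i] = std::make_pair(ranks(d, g), absz(d, g));
  }
  std::sort(h.begin(), h.end());
  double sw = 0.0;
  for (int i = 0; i < m; ++i) sw += h[i].second;
  const double miss = 1.0 / (double)(G - m);
  double cum = 0.0, best = 0.0, besta = -1.0;
  for (int i = 0; i < m; ++i) {
    const double drop = (h[i].first - (i + 1)) * miss;
    const double before = cum - drop;
    cum += (sw > 0.0) ? h[i].second / sw : 1.0 / m;
    const double after = cum - drop;
    if (std::fabs(before) > besta) { besta = std::fabs(before); best = before; }
    if (std::fabs(after) > besta) { besta = std::fabs(after); best = after; }
  }
  return best;
}

// WTCS of every query (up/down index pair) against every drug of a
// pre-ranked reference.  ranks: drug x gene rank positions (1 = highest z);
// absz: drug x gene |z|; ups/downs: lists of 1-based gene column indices.
// [[Rcpp::export(name = ".wtcs_batch_cpp")]]
NumericMatrix wtcs_batch_cpp(IntegerMatrix ranks, NumericMatrix absz,
                             List ups, List downs) {
  const int D = ranks.nrow(), G = ranks.ncol();
  const int N = ups.size();
  NumericMatrix out(D, N);
  for (int q = 0; q < N; ++q) {
    IntegerVector up = ups[q];
    IntegerVector dn = downs[q];
    for (int d = 0; d < D; ++d) {
      const double eu = es_one(ranks, absz, d, up, G);
      const double ed = es_one(ranks, absz, d, dn, G);
      double w = 0.0;
      if (eu == 0.0 || ed == 0.0 || ((eu > 0.0) != (ed > 0.0)))
        w = (eu - ed) / 2.0;
      out(d, q) = w;
    }
  }
  return out;
}
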