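// 3x3 median filter with edge replication (sorting-network median of 9).
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static inline void mmswap(double &a, double &b) { if (b < a) std::swap(a, b); }

static inline double med9(double p[9]) {
  mmswap(p[1], p[2]); mmswap(p[4], p[5]); mmswap(p[7], p[8]);
  mmswap(p[0], p[1]); mmswap(p[3], p[4]); mmswap(p[6], p[7]);
  mmswap(p[1], p[2]); mmswap(p[4], p[5]); mmswap(p[7], p[8]);
  mmswap(p[0], p[3]); mmswap(p[5], p[8]); mmswap(p[4], p[7]);
  mmswap(p[3], p[6]); mmswap(p[1], p[4]); mmswap(p[2], p[5]);
  mmswap(p[4], p[7]); mmswap(p[4], p[2]); mmswap(p[6], p[4]);
  mmswap(p[4], p[2]);
  return p[4];
}

// [[Rcpp::export]]
NumericMatrix cpp_median3(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double p[9];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int t = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = std::min(std::max(c + dc, 0), nc - 1);
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = std::min(std::max(r + dr, 0), nr - 1);
          p[t++] = img(rr, cc);
        }
      }
      out(r, c) = med9(p);
    }
  }
  return out;
}
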