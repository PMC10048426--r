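#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Reflect (symmetric, edge-including) index into [0, n).
static inline int reflect_idx(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// 5x5 median filter of one channel, reflect padding at the borders.
// Input/output are numeric matrices holding 8-bit values.
// [[Rcpp::export]]
NumericMatrix median5_channel(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double buf[25];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -2; dc <= 2; ++dc) {
        const int cc = reflect_idx(c + dc, nc);
        for (int dr = -2; dr <= 2; ++dr) {
          buf[k++] = x(reflect_idx(r + dr, nr), cc);
        }
      }
      std::nth_element(buf, buf + 12, buf + 25);
      out(r, c) = buf[12];
    }
  }
  return out;
}
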