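#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Reflect an index into [0, n-1] (edge-repeating symmetric padding).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  int j = ((i % period) + period) % period;
  return (j < n) ? j : (period - 1 - j);
}

// Median filter with an odd k x k window and reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int k) {
  if (k % 2 == 0) stop("kernel size must be odd");
  int h = x.nrow(), w = x.ncol(), r = k / 2;
  NumericMatrix out(h, w);
  std::vector<double> buf(k * k);
  for (int c = 0; c < w; ++c) {
    for (int rI = 0; rI < h; ++rI) {
      int m = 0;
      for (int dc = -r; dc <= r; ++dc) {
        int cc = reflect_idx(c + dc, w);
        for (int dr = -r; dr <= r; ++dr) {
          buf[m++] = x(reflect_idx(rI + dr, h), cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = (med + lo) / 2.0;
      }
      out(rI, c) = med;
    }
  }
  return out;
}
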