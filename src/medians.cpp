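#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-pixel median across frames: X is (n_pixels x n_frames); returns the
// median of each row. Used for background estimation over ~2e5 pixels where
// apply(X, 1, median) is prohibitively slow.
// [[Rcpp::export]]
NumericVector row_medians(NumericMatrix X) {
  const int n = X.nrow(), k = X.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = X(i, j);
    const int h = k / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (k % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[i] = m;
  }
  return out;
}
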