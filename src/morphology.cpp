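#include <Rcpp.h>
using namespace Rcpp;

// Flat structuring element of `window` samples (odd), replicate-edge padding.
// O(n * window) is ample for spectra of a few tens of thousands of points.
static NumericVector run_extreme(const NumericVector& x, int window, bool maximum) {
  const int n = x.size();
  const int h = window / 2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int j = i - h; j <= i + h; ++j) {
      int jj = j < 0 ? 0 : (j >= n ? n - 1 : j);
      double xv = x[jj];
      if (maximum ? (xv > v) : (xv < v)) v = xv;
    }
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector morph_erode(NumericVector x, int window) {
  return run_extreme(x, window, false);
}

// [[Rcpp::export]]
NumericVector morph_dilate(NumericVector x, int window) {
  return run_extreme(x, window, true);
}
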