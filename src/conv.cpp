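#include <Rcpp.h>
using namespace Rcpp;

// Gather convolution taps into an im2col matrix.
// Xpad: padded stacked rows (n_pad x cin); rows0: 1-based padded row of the
// first tap for each output position; tap_off: 0-based offsets per tap.
// Returns (length(rows0)) x (k * cin) with column block j holding tap j.
// [[Rcpp::export]]
NumericMatrix im2col_gather(NumericMatrix Xpad, IntegerVector rows0,
                            IntegerVector tap_off) {
  int n = rows0.size(), k = tap_off.size(), cin = Xpad.ncol();
  int npad = Xpad.nrow();
  NumericMatrix cols(n, k * cin);
  for (int j = 0; j < k; ++j) {
    int off = tap_off[j];
    for (int c = 0; c < cin; ++c) {
      const double* src = &Xpad(0, c);
      double* dst = &cols(0, j * cin + c);
      for (int i = 0; i < n; ++i) {
        int r = rows0[i] - 1 + off;
        dst[i] = (r >= 0 && r < npad) ? src[r] : 0.0;
      }
    }
  }
  return cols;
}

// Scatter-add the im2col gradient back onto the padded rows.
// [[Rcpp::export]]
NumericMatrix col2im_scatter(NumericMatrix dcols, IntegerVector rows0,
                             IntegerVector tap_off, int n_pad, int cin) {
  int n = rows0.size(), k = tap_off.size();
  NumericMatrix dXpad(n_pad, cin);
  for (int j = 0; j < k; ++j) {
    int off = tap_off[j];
    for (int c = 0; c < cin; ++c) {
      const double* src = &dcols(0, j * cin + c);
      double* dst = &dXpad(0, c);
      for (int i = 0; i < n; ++i) {
        int r = rows0[i] - 1 + off;
        if (r >= 0 && r < n_pad) dst[r] += src[i];
      }
    }
  }
  return dXpad;
}
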