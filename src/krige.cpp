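#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Block-kriging grid predictions given the precomputed row vector
// v = (z, 0)' A^{-1} of the ordinary-kriging system (correlation scale):
// prediction(cell) = sum_i v_i * c0_i(cell) + v_n (c0 is the sample-to-block
// correlation averaged over the 2 x 2 sub-point layout).
// [[Rcpp::export]]
NumericVector krige_grid(NumericVector sx, NumericVector sy,
                         NumericVector v,
                         NumericVector gx, NumericVector gy,
                         double off, double range) {
  const int n = sx.size(), m = gx.size();
  NumericVector out(m);
  const double sub[4][2] = {{-off, -off}, {off, -off}, {-off, off}, {off, off}};
  for (int c = 0; c < m; c++) {
    double acc = v[n];  // Lagrange-multiplier slot times the constraint 1
    for (int i = 0; i < n; i++) {
      double c0 = 0.0;
      for (int q = 0; q < 4; q++) {
        double dx = sx[i] - (gx[c] + sub[q][0]);
        double dy = sy[i] - (gy[c] + sub[q][1]);
        c0 += std::exp(-std::sqrt(dx * dx + dy * dy) / range);
      }
      acc += v[i] * c0 * 0.25;
    }
    out[c] = acc;
  }
  return out;
}
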