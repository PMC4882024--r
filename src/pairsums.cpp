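#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Fraction-of-circle-inside-rectangle reciprocal (Ripley's isotropic weight)
// for centre (xi, yi), radius r in [x0,x1] x [y0,y1]. Valid for r < min(side);
// the inside fraction is floored to avoid blow-up for near-degenerate cases.
static double iso_weight(double xi, double yi, double r,
                         double x0, double x1, double y0, double y1) {
  if (r <= 0.0) return 1.0;
  double d[4] = { xi - x0, x1 - xi, yi - y0, y1 - yi };
  double alpha[4];
  double outside = 0.0;
  for (int k = 0; k < 4; k++) {
    if (d[k] < r) {
      double c = d[k] / r;
      if (c < -1.0) c = -1.0;
      alpha[k] = std::acos(c);
    } else alpha[k] = 0.0;
    outside += 2.0 * alpha[k];
  }
  // adjacent edge pairs share a corner; subtract double-counted overlap arcs
  const int ci[4] = {0, 0, 1, 1}, cj[4] = {2, 3, 2, 3};
  for (int k = 0; k < 4; k++) {
    double ov = alpha[ci[k]] + alpha[cj[k]] - M_PI / 2.0;
    if (ov > 0.0) outside -= ov;
  }
  double frac = 1.0 - outside / (2.0 * M_PI);
  if (frac < 1e-6) frac = 1e-6;
  return 1.0 / frac;
}

static inline double pair_weight(int corr, double xi, double yi,
                                 double dx, double dy, double dd,
                                 double x0, double x1, double y0, double y1,
                                 double a, double b, double area) {
  if (corr == 1) return iso_weight(xi, yi, dd, x0, x1, y0, y1);
  if (corr == 2) return area / ((a - std::fabs(dx)) * (b - std::fabs(dy)));
  return 1.0;
}

// Cumulative weighted pair counts: returns S(r_k) = sum over ordered pairs
// i != j with d_ij <= r_k of e_ij [/ (lambda_i * lambda_j)].
// correction: 0 none, 1 isotropic, 2 translation.
// [[Rcpp::export]]
NumericVector pair_count_cum(NumericVector x, NumericVector y,
                             NumericVector r,
                             double x0, double x1, double y0, double y1,
                             int correction,
                             Nullable<NumericVector> lambda_ = R_NilValue) {
  const int n = x.size(), nr = r.size();
  const double a = x1 - x0, b = y1 - y0, area = a * b;
  const double rmax = r[nr - 1];
  bool inhom = lambda_.isNotNull();
  NumericVector lambda;
  if (inhom) lambda = NumericVector(lambda_);
  std::vector<double> acc(nr, 0.0);
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double dd = std::sqrt(dx * dx + dy * dy);
      if (dd > rmax) continue;
      double wij = pair_weight(correction, x[i], y[i], dx, dy, dd,
                               x0, x1, y0, y1, a, b, area);
      double wji = (correction == 1)
        ? pair_weight(correction, x[j], y[j], dx, dy, dd, x0, x1, y0, y1, a, b, area)
        : wij;
      double w = wij + wji;
      if (inhom) w /= lambda[i] * lambda[j];
      int lo = std::lower_bound(r.begin(), r.end(), dd) - r.begin();
      if (lo < nr) acc[lo] += w;
    }
  }
  NumericVector S(nr);
  double cum = 0.0;
  for (int k = 0; k < nr; k++) { cum += acc[k]; S[k] = cum; }
  return S;
}

// Epanechnikov-kernel pair sums for the pair correlation function:
// S(r_k) = sum over ordered pairs of e_ij * k_h(r_k - d_ij) [/ (lambda_i lambda_j)].
// [[Rcpp::export]]
NumericVector pair_kernel_sum(NumericVector x, NumericVector y,
                              NumericVector r, double h,
                              double x0, double x1, double y0, double y1,
                              int correction,
                              Nullable<NumericVector> lambda_ = R_NilValue) {
  const int n = x.size(), nr = r.size();
  const double a = x1 - x0, b = y1 - y0, area = a * b;
  const double rmax = r[nr - 1] + h;
  bool inhom = lambda_.isNotNull();
  NumericVector lambda;
  if (inhom) lambda = NumericVector(lambda_);
  NumericVector S(nr);
  const double c0 = 0.75 / h;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double dd = std::sqrt(dx * dx + dy * dy);
      if (dd > rmax) continue;
      double wij = pair_weight(correction, x[i], y[i], dx, dy, dd,
                               x0, x1, y0, y1, a, b, area);
      double wji = (correction == 1)
        ? pair_weight(correction, x[j], y[j], dx, dy, dd, x0, x1, y0, y1, a, b, area)
        : wij;
      double w = wij + wji;
      if (inhom) w /= lambda[i] * lambda[j];
      // kernel support is [dd - h, dd + h] on the r grid
      int klo = std::lower_bound(r.begin(), r.end(), dd - h) - r.begin();
      for (int k = klo; k < nr; k++) {
        double t = (r[k] - dd) / h;
        if (t > 1.0) break;
        S[k] += w * c0 * (1.0 - t * t);
      }
    }
  }
  return S;
}
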