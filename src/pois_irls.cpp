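#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted Poisson IRLS for the Berman-Turner quadrature GLM.
// Solves via normal equations with a Cholesky factorization; p is small
// (<= 15 terms) so this is both stable enough and far faster than the
// generic GLM path. Returns NULL-equivalent flag on singular designs.
// [[Rcpp::export]]
List pois_irls(NumericMatrix X, NumericVector y, NumericVector w,
               int maxit = 60, double tol = 1e-11) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(p, 0.0), betanew(p), eta(n), mu(n);
  // start: intercept at log of weighted mean response
  double sy = 0, sw = 0;
  for (int i = 0; i < n; i++) { sy += w[i] * y[i]; sw += w[i]; }
  beta[0] = std::log(std::max(sy / sw, 1e-12));
  std::vector<double> XtWX(p * p), XtWz(p);
  bool converged = false;
  for (int it = 0; it < maxit; it++) {
    for (int i = 0; i < n; i++) {
      double e = 0;
      for (int k = 0; k < p; k++) e += X(i, k) * beta[k];
      if (e > 30) e = 30; if (e < -30) e = -30;
      eta[i] = e; mu[i] = std::exp(e);
    }
    std::fill(XtWX.begin(), XtWX.end(), 0.0);
    std::fill(XtWz.begin(), XtWz.end(), 0.0);
    for (int i = 0; i < n; i++) {
      double wi = w[i] * mu[i];
      double zi = eta[i] + (y[i] - mu[i]) / mu[i];
      for (int k = 0; k < p; k++) {
        double xik = X(i, k);
        XtWz[k] += wi * zi * xik;
        for (int l = k; l < p; l++) XtWX[k * p + l] += wi * xik * X(i, l);
      }
    }
    // Cholesky of the upper-triangular-stored XtWX
    std::vector<double> L(p * p, 0.0);
    bool ok = true;
    for (int k = 0; k < p && ok; k++) {
      double d = XtWX[k * p + k];
      for (int m = 0; m < k; m++) d -= L[k * p + m] * L[k * p + m];
      if (d <= 1e-12) { ok = false; break; }
      L[k * p + k] = std::sqrt(d);
      for (int l = k + 1; l < p; l++) {
        double s = XtWX[k * p + l];
        for (int m = 0; m < k; m++) s -= L[l * p + m] * L[k * p + m];
        L[l * p + k] = s / L[k * p + k];
      }
    }
    if (!ok)
      return List::create(_["coefficients"] = R_NilValue,
                          _["converged"] = false,
                          _["singular"] = true);
    // forward/back substitution
    std::vector<double> tmp(p);
    for (int k = 0; k < p; k++) {
      double s = XtWz[k];
      for (int m = 0; m < k; m++) s -= L[k * p + m] * tmp[m];
      tmp[k] = s / L[k * p + k];
    }
    for (int k = p - 1; k >= 0; k--) {
      double s = tmp[k];
      for (int m = k + 1; m < p; m++) s -= L[m * p + k] * betanew[m];
      betanew[k] = s / L[k * p + k];
    }
    double delta = 0;
    for (int k = 0; k < p; k++)
      delta = std::max(delta, std::fabs(betanew[k] - beta[k]) /
                       (std::fabs(beta[k]) + 0.1));
    beta = betanew;
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["coefficients"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = converged,
                      _["singular"] = false);
}
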