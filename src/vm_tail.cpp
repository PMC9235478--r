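#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Gauss series for 2F1(a, b; c; z), 0 <= z < 1, parameters positive.
// Converges geometrically with ratio <= z here because b/c -> 1.
static double gauss_series(double a, double b, double c, double z,
                           double eps, int cap) {
  double term = 1.0, sum = 1.0;
  for (int n = 0; n < cap; ++n) {
    term *= (a + n) * (b + n) / ((c + n) * (1.0 + n)) * z;
    sum += term;
    if (std::fabs(term) < eps * std::fabs(sum)) break;
  }
  return sum;
}

// Value at z = 1: 2F1(a,b;c;1) = G(c)G(c-a-b) / (G(c-a)G(c-b)).
// For a = 1/2, b = (j+1)/2, c = (j+3)/2: c-a-b = 1/2, c-b = 1, so
// H_j(1) = sqrt(pi) * G((j+3)/2) / G((j+2)/2).
static double hyp_half_at_one(int j) {
  return std::sqrt(M_PI) *
         std::exp(std::lgamma(0.5 * (j + 3)) - std::lgamma(0.5 * (j + 2)));
}

// H_j(z) = 2F1(1/2, (j+1)/2; (j+3)/2; z) on [0, 1].
// Near z = 1 the direct series is slow; switch to the linear 1-z
// transformation, where the first 2F1 collapses to (1-s)^{-b} because
// a + b - c + 1 = a, and the second has parameters (1, (j+2)/2; 3/2).
static double hyp_half(int j, double z, double eps) {
  const double b = 0.5 * (j + 1), c = 0.5 * (j + 3);
  if (z >= 1.0) return hyp_half_at_one(j);
  if (z <= 0.8) return gauss_series(0.5, b, c, z, eps, 2000);
  const double s = 1.0 - z;
  const double t1 = hyp_half_at_one(j) * std::pow(z, -b);
  // G(c)G(-1/2)/(G(1/2)G(b)) = -2 G(c)/G(b)
  const double coef2 = -2.0 * std::exp(std::lgamma(c) - std::lgamma(b));
  const double t2 =
      std::sqrt(s) * coef2 * gauss_series(1.0, 0.5 * (j + 2), 1.5, s, eps, 2000);
  return t1 + t2;
}

//' @title von Mises upper tail by term-wise series integration (C++ core)
//' @description Computes P(deviation >= theta) for a mean-zero von Mises
//'   variable via the series expansion of exp(kappa * cos(t)), integrated
//'   term by term with the hypergeometric antiderivative
//'   -cot(t)|sin(t)| (k cos t)^j 2F1(1/2,(j+1)/2;(j+3)/2;cos^2 t) / G(j+2).
//'   All terms are scaled by exp(-kappa) to avoid overflow; the scale
//'   cancels in the tail ratio. Not exported; see vm_tail_pvalue().
// [[Rcpp::export]]
NumericVector vm_tail_cpp(NumericVector theta, NumericVector kappa,
                          double tol, int max_terms) {
  const R_xlen_t n = theta.size();
  NumericVector out(n);
  const double eps2f1 = 1e-15;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double th = theta[i], k = kappa[i];
    if (ISNAN(th) || ISNAN(k)) { out[i] = NA_REAL; continue; }
    if (th <= 0.0) { out[i] = 1.0; continue; }
    if (th >= M_PI) { out[i] = 0.0; continue; }
    const double c0 = std::cos(th), z = c0 * c0;
    const double logk = (k > 0.0) ? std::log(k) : R_NegInf;
    double num = 0.0, den = 0.0;
    bool converged = false;
    for (int j = 0; j < max_terms; ++j) {
      // scaled series weight k^j e^{-k} / Gamma(j + 2)
      const double lw = (j == 0 ? 0.0 : j * logk) - std::lgamma(j + 2.0) - k;
      const double w = std::exp(lw);
      const double h1 = hyp_half_at_one(j);
      const double sgn = (j % 2 == 0) ? 1.0 : -1.0;
      // antiderivative at pi minus antiderivative at theta (resp. 0)
      const double term_num = w * (sgn * h1 + std::pow(c0, j + 1) * hyp_half(j, z, eps2f1));
      const double term_den = (j % 2 == 0) ? 2.0 * w * h1 : 0.0;
      num += term_num;
      den += term_den;
      // terms grow until j ~ kappa, so only test convergence past the peak
      if (j >= (int)k && std::fabs(term_num) < tol && term_den < tol) {
        converged = true;
        break;
      }
    }
    if (!converged)
      stop("von Mises tail series did not converge within %d terms (kappa = %g, theta = %g)",
           max_terms, k, th);
    double p = num / den;
    if (p < 0.0) p = 0.0;
    if (p > 1.0) p = 1.0;
    out[i] = p;
  }
  return out;
}
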