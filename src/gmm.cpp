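// EM inner loop for a 2-component 1-D Gaussian mixture.  Kept in C++ because
// the classifier runs it with multiple restarts over 1e4-cell samples inside
// sweeps and calibration loops.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_gmm2_em(NumericVector x, double mu1, double mu2, double sg1,
                 double sg2, double w1, double var_floor, int max_iter,
                 double tol) {
  int n = x.size();
  const double log2pi = std::log(2.0 * M_PI);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  std::vector<double> g1(n);
  for (int it = 0; it < max_iter; ++it) {
    double lw1 = std::log(w1), lw2 = std::log(1.0 - w1);
    double ls1 = std::log(sg1), ls2 = std::log(sg2);
    ll = 0.0;
    double n1 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double z1 = (x[i] - mu1) / sg1, z2 = (x[i] - mu2) / sg2;
      double lp1 = lw1 - 0.5 * (z1 * z1 + log2pi) - ls1;
      double lp2 = lw2 - 0.5 * (z2 * z2 + log2pi) - ls2;
      double m = lp1 > lp2 ? lp1 : lp2;
      double den = m + std::log(std::exp(lp1 - m) + std::exp(lp2 - m));
      ll += den;
      double g = std::exp(lp1 - den);
      g1[i] = g;
      n1 += g;
      s1 += g * x[i];
      s2 += (1.0 - g) * x[i];
    }
    double n2 = n - n1;
    if (n1 < 1e-8 || n2 < 1e-8) { ll = R_NegInf; break; }
    mu1 = s1 / n1;
    mu2 = s2 / n2;
    double v1 = 0.0, v2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - mu1, d2 = x[i] - mu2;
      v1 += g1[i] * d1 * d1;
      v2 += (1.0 - g1[i]) * d2 * d2;
    }
    sg1 = std::sqrt(std::max(v1 / n1, var_floor));
    sg2 = std::sqrt(std::max(v2 / n2, var_floor));
    w1 = n1 / n;
    if (R_finite(ll) && it > 0 && ll - ll_old < tol * (std::fabs(ll_old) + 1.0)) {
      converged = true;
      break;
    }
    ll_old = ll;
  }
  return List::create(_["w1"] = w1, _["mu1"] = mu1, _["mu2"] = mu2,
                      _["sg1"] = sg1, _["sg2"] = sg2, _["loglik"] = ll,
                      _["converged"] = converged);
}
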