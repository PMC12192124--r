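// Cyclic coordinate descent over a decreasing lambda path with warm
// starts, on Gram-matrix (covariance) updates for standardized columns.
// Hot loop of the penalized VAR(1) solver; mirrors the closed-form
// univariate thresholds of univariate_threshold().
#include <Rcpp.h>
using namespace Rcpp;

static inline double threshold1_cpp(double z, double lam, int kind,
                                    double a) {
  double az = std::fabs(z);
  double sgn = (z > 0) - (z < 0);
  if (kind == 0) {  // lasso
    return az <= lam ? 0.0 : sgn * (az - lam);
  }
  if (kind == 1) {  // scad
    if (az <= 2.0 * lam) {
      return az <= lam ? 0.0 : sgn * (az - lam);
    }
    if (az <= a * lam) {
      double s = az - a * lam / (a - 1.0);
      if (s < 0) s = 0;
      return sgn * s * (a - 1.0) / (a - 2.0);
    }
    return z;
  }
  // mcp
  if (az <= a * lam) {
    return az <= lam ? 0.0 : sgn * (az - lam) * a / (a - 1.0);
  }
  return z;
}

// [[Rcpp::export]]
List cd_solve_path(const NumericMatrix& gram, const NumericVector& xty,
                   const NumericVector& lambda, int kind, double a,
                   double tol, int max_iter) {
  int p = xty.size();
  int nl = lambda.size();
  NumericMatrix out(p, nl);
  IntegerVector iters(nl);
  std::vector<double> beta(p, 0.0);
  for (int i = 0; i < nl; ++i) {
    double lam = lambda[i];
    int it = 0;
    while (it < max_iter) {
      ++it;
      double delta = 0.0;
      for (int j = 0; j < p; ++j) {
        double bj = beta[j];
        double z = xty[j] + bj;
        const double* gcol = &gram(0, j);
        for (int k = 0; k < p; ++k) z -= gcol[k] * beta[k];
        double nb = threshold1_cpp(z, lam, kind, a);
        if (nb != bj) {
          beta[j] = nb;
          double d = std::fabs(nb - bj);
          if (d > delta) delta = d;
        }
      }
      if (delta < tol) break;
    }
    iters[i] = it;
    for (int j = 0; j < p; ++j) out(j, i) = beta[j];
  }
  return List::create(_["beta"] = out, _["iters"] = iters);
}
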