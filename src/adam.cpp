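#include <Rcpp.h>
#include <cmath>

// In-place Adam update: one fused pass over parameter, moment and gradient
// buffers. The R wrapper guarantees exclusive ownership of p, m and v.
// [[Rcpp::export]]
void adam_update_inplace(Rcpp::NumericVector p, Rcpp::NumericVector m,
                         Rcpp::NumericVector v, Rcpp::NumericVector g,
                         double lr, double beta1, double beta2, double eps,
                         double bc1, double bc2) {
  const R_xlen_t n = p.size();
  double *pp = p.begin(), *pm = m.begin(), *pv = v.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
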