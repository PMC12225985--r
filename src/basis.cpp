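#include <Rcpp.h>
#include <cmath>

// Lesion-centric radial basis: for each radius r_k, a B x V matrix of
// clamped linear ramps ((r_k - rho)/tau + 0.5) with rho the distance from
// each case's mask center to every voxel center. One fused pass avoids the
// large temporary distance matrices an R implementation needs.
// [[Rcpp::export]]
Rcpp::List radial_basis_cpp(Rcpp::NumericMatrix centers,
                            Rcpp::NumericMatrix coords,
                            Rcpp::NumericVector radii, double tau) {
  const int B = centers.nrow();
  const R_xlen_t V = coords.nrow();
  const int K = radii.size();
  Rcpp::List out(K);
  std::vector<double *> ptr(K);
  for (int k = 0; k < K; ++k) {
    Rcpp::NumericMatrix m(B, (int)V);
    out[k] = m;
    ptr[k] = m.begin();
  }
  const double *cx = &coords(0, 0), *cy = &coords(0, 1), *cz = &coords(0, 2);
  const double *bx = &centers(0, 0), *by = &centers(0, 1),
               *bz = &centers(0, 2);
  const double rmax_support = radii[K - 1] + tau;
  for (R_xlen_t v = 0; v < V; ++v) {
    const double vx = cx[v], vy = cy[v], vz = cz[v];
    const R_xlen_t col = v * B;
    for (int b = 0; b < B; ++b) {
      const double dx = vx - bx[b], dy = vy - by[b], dz = vz - bz[b];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rmax_support * rmax_support) continue;  // all zero
      const double rho = std::sqrt(r2);
      for (int k = 0; k < K; ++k) {
        double m = (radii[k] - rho) / tau + 0.5;
        if (m < 0.0) m = 0.0; else if (m > 1.0) m = 1.0;
        ptr[k][col + b] = m;
      }
    }
  }
  return out;
}
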