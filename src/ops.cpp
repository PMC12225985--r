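#include <Rcpp.h>

// out[b, v] = sum_k a[b, k] * phi_k[b, v]
// [[Rcpp::export]]
Rcpp::NumericMatrix radial_forward_cpp(Rcpp::NumericMatrix a,
                                       Rcpp::List phi) {
  const int B = a.nrow(), K = a.ncol();
  Rcpp::NumericMatrix phi0 = phi[0];
  const R_xlen_t V = phi0.ncol();
  Rcpp::NumericMatrix out(B, (int)V);
  double *po = out.begin();
  for (int k = 0; k < K; ++k) {
    Rcpp::NumericMatrix pk = phi[k];
    const double *pp = pk.begin();
    const double *pa = &a(0, k);
    for (R_xlen_t v = 0; v < V; ++v) {
      double *o = po + v * B;
      const double *p = pp + v * B;
      for (int b = 0; b < B; ++b) o[b] += pa[b] * p[b];
    }
  }
  return out;
}

// ga[b, k] = sum_v g[b, v] * phi_k[b, v]
// [[Rcpp::export]]
Rcpp::NumericMatrix radial_backward_cpp(Rcpp::NumericMatrix g,
                                        Rcpp::List phi) {
  const int B = g.nrow();
  const R_xlen_t V = g.ncol();
  const int K = phi.size();
  Rcpp::NumericMatrix ga(B, K);
  const double *pg = g.begin();
  for (int k = 0; k < K; ++k) {
    Rcpp::NumericMatrix pk = phi[k];
    const double *pp = pk.begin();
    double *out = &ga(0, k);
    for (R_xlen_t v = 0; v < V; ++v) {
      const double *gv = pg + v * B;
      const double *p = pp + v * B;
      for (int b = 0; b < B; ++b) out[b] += gv[b] * p[b];
    }
  }
  return ga;
}

// Separable 3-D smoothing of flattened volumes (rows of x, grid order
// x-fastest), multiplying along each axis by the given smoothing matrix
// (or its transpose): y[i'] = sum_i K[i', i] x[i]. Works in place on a
// copy, axis by axis, without the memory reshuffles an R implementation
// needs.
static void blur_axis(std::vector<double> &buf, std::vector<double> &tmp,
                      const Rcpp::NumericMatrix &K, bool transpose,
                      int B, int nx, int ny, int nz, int axis) {
  const int n = (axis == 0) ? nx : (axis == 1 ? ny : nz);
  std::fill(tmp.begin(), tmp.end(), 0.0);
  // copy the (possibly transposed) kernel once; it is banded, so record
  // each output row's nonzero column range
  std::vector<double> Kd((size_t)n * n);
  std::vector<int> lo(n), hi(n);
  for (int ip = 0; ip < n; ++ip) {
    lo[ip] = n; hi[ip] = -1;
    for (int i = 0; i < n; ++i) {
      const double w = transpose ? K(i, ip) : K(ip, i);
      Kd[(size_t)ip * n + i] = w;
      if (w != 0.0) { if (i < lo[ip]) lo[ip] = i; if (i > hi[ip]) hi[ip] = i; }
    }
  }
  if (axis == 0) {
    const R_xlen_t plane = (R_xlen_t)B * nx;
    for (R_xlen_t q = 0; q < (R_xlen_t)ny * nz; ++q) {
      const double *src = buf.data() + q * plane;
      double *dst = tmp.data() + q * plane;
      for (int ip = 0; ip < n; ++ip) {
        double *d = dst + (R_xlen_t)B * ip;
        const double *krow = Kd.data() + (size_t)ip * n;
        for (int i = lo[ip]; i <= hi[ip]; ++i) {
          const double w = krow[i];
          const double *srow = src + (R_xlen_t)B * i;
          for (int b = 0; b < B; ++b) d[b] += w * srow[b];
        }
      }
    }
  } else if (axis == 1) {
    const R_xlen_t row = (R_xlen_t)B * nx;
    const R_xlen_t plane = row * ny;
    for (int iz = 0; iz < nz; ++iz) {
      const double *src = buf.data() + (R_xlen_t)iz * plane;
      double *dst = tmp.data() + (R_xlen_t)iz * plane;
      for (int ip = 0; ip < n; ++ip) {
        double *d = dst + row * ip;
        const double *krow = Kd.data() + (size_t)ip * n;
        for (int i = lo[ip]; i <= hi[ip]; ++i) {
          const double w = krow[i];
          const double *srow = src + row * i;
          for (R_xlen_t t = 0; t < row; ++t) d[t] += w * srow[t];
        }
      }
    }
  } else {
    const R_xlen_t plane = (R_xlen_t)B * nx * ny;
    for (int ip = 0; ip < n; ++ip) {
      double *d = tmp.data() + plane * ip;
      const double *krow = Kd.data() + (size_t)ip * n;
      for (int i = lo[ip]; i <= hi[ip]; ++i) {
        const double w = krow[i];
        const double *srow = buf.data() + plane * i;
        for (R_xlen_t t = 0; t < plane; ++t) d[t] += w * srow[t];
      }
    }
  }
  buf.swap(tmp);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix blur_rows_cpp(Rcpp::NumericMatrix x, int nx, int ny,
                                  int nz, Rcpp::NumericMatrix Kx,
                                  Rcpp::NumericMatrix Ky,
                                  Rcpp::NumericMatrix Kz, bool transpose) {
  const int B = x.nrow();
  const R_xlen_t total = (R_xlen_t)B * nx * ny * nz;
  std::vector<double> buf(x.begin(), x.begin() + total);
  std::vector<double> tmp(total);
  blur_axis(buf, tmp, Kx, transpose, B, nx, ny, nz, 0);
  blur_axis(buf, tmp, Ky, transpose, B, nx, ny, nz, 1);
  blur_axis(buf, tmp, Kz, transpose, B, nx, ny, nz, 2);
  Rcpp::NumericMatrix out(B, (int)(total / B));
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}
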