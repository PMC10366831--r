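#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix construction for 3x3x3 convolutions with zero padding 1.
// Input a: 4D array (nx, ny, nz, C); output: matrix (nx*ny*nz, 27*C) whose
// column order is (ox fastest, oy, oz, then channel).
// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector a) {
  IntegerVector d = a.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], C = d[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix M(nvox, 27 * C);
  const double *pa = REAL(a);
  double *pm = REAL(M);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const double *ac = pa + (R_xlen_t)c * nvox;
    for (int oz = -1; oz <= 1; ++oz)
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox, ++col) {
          double *mc = pm + (R_xlen_t)col * nvox;
          R_xlen_t i = 0;
          for (int z = 0; z < nz; ++z) {
            int zs = z + oz;
            for (int y = 0; y < ny; ++y) {
              int ys = y + oy;
              bool inyz = zs >= 0 && zs < nz && ys >= 0 && ys < ny;
              const double *row =
                  inyz ? ac + ((R_xlen_t)zs * ny + ys) * nx : NULL;
              for (int x = 0; x < nx; ++x, ++i) {
                int xs = x + ox;
                mc[i] = (inyz && xs >= 0 && xs < nx) ? row[xs] : 0.0;
              }
            }
          }
        }
  }
  return M;
}

// Adjoint of im2col3_cpp: scatter-add patch-matrix gradients back onto the
// input grid. dims = c(nx, ny, nz, C).
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix M, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out((R_xlen_t)nvox * C);
  out.attr("dim") = dims;
  double *po = REAL(out);
  const double *pm = REAL(M);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    double *oc = po + (R_xlen_t)c * nvox;
    for (int oz = -1; oz <= 1; ++oz)
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox, ++col) {
          const double *mc = pm + (R_xlen_t)col * nvox;
          R_xlen_t i = 0;
          for (int z = 0; z < nz; ++z) {
            int zs = z + oz;
            if (zs < 0 || zs >= nz) { i += (R_xlen_t)ny * nx; continue; }
            for (int y = 0; y < ny; ++y) {
              int ys = y + oy;
              if (ys < 0 || ys >= ny) { i += nx; continue; }
              double *row = oc + ((R_xlen_t)zs * ny + ys) * nx;
              for (int x = 0; x < nx; ++x, ++i) {
                int xs = x + ox;
                if (xs >= 0 && xs < nx) row[xs] += mc[i];
              }
            }
          }
        }
  }
  return out;
}
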