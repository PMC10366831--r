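#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact line integral of a piecewise-constant voxel volume along the
// segment src -> dst (world mm), Siddon-style incremental traversal.
// mu is a 3D array (nx, ny, nz) of linear attenuation coefficients (1/mm),
// with voxel (0,0,0) spanning [origin, origin + voxel] per axis.
static double siddon_one(const double *mu, const int *dims, double voxel,
                         const double *origin, const double *src,
                         const double *dst) {
  double dir[3], lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    dir[a] = dst[a] - src[a];
    lo[a] = origin[a];
    hi[a] = origin[a] + dims[a] * voxel;
  }
  double norm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                          dir[2] * dir[2]);
  if (norm == 0.0) return 0.0;

  // clip the parametric range [0, 1] to the volume slab per axis
  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (src[a] <= lo[a] || src[a] >= hi[a]) return 0.0;
    } else {
      double t0 = (lo[a] - src[a]) / dir[a];
      double t1 = (hi[a] - src[a]) / dir[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  if (tmin >= tmax) return 0.0;

  // per-axis parametric step across one voxel and next crossing after tmin
  double tnext[3], dt[3];
  int idx[3], step[3];
  const double eps = 1e-12;
  double tmid = tmin + eps;
  for (int a = 0; a < 3; ++a) {
    double p = src[a] + tmid * dir[a];
    int i = (int)std::floor((p - origin[a]) / voxel);
    if (i < 0) i = 0;
    if (i >= dims[a]) i = dims[a] - 1;
    idx[a] = i;
    if (std::fabs(dir[a]) < 1e-12) {
      step[a] = 0;
      dt[a] = R_PosInf;
      tnext[a] = R_PosInf;
    } else {
      step[a] = dir[a] > 0 ? 1 : -1;
      dt[a] = voxel / std::fabs(dir[a]);
      int nextplane = dir[a] > 0 ? i + 1 : i;
      tnext[a] = (origin[a] + nextplane * voxel - src[a]) / dir[a];
      while (tnext[a] <= tmin) tnext[a] += dt[a];
    }
  }

  double acc = 0.0, t = tmin;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  while (t < tmax - eps) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double tstop = tnext[a] < tmax ? tnext[a] : tmax;
    double len = (tstop - t) * norm;
    if (len > 0 && idx[0] >= 0 && idx[0] < nx && idx[1] >= 0 &&
        idx[1] < ny && idx[2] >= 0 && idx[2] < nz) {
      acc += len * mu[idx[0] + nx * (idx[1] + (R_xlen_t)ny * idx[2])];
    }
    t = tstop;
    if (tnext[a] <= tmax) {
      idx[a] += step[a];
      tnext[a] += dt[a];
      if (idx[a] < 0 || idx[a] >= dims[a]) break;
    }
  }
  return acc;
}

// [[Rcpp::export]]
double siddon_ray_cpp(NumericVector mu, double voxel, NumericVector origin,
                      NumericVector src, NumericVector dst) {
  IntegerVector d = mu.attr("dim");
  int dims[3] = {d[0], d[1], d[2]};
  return siddon_one(REAL(mu), dims, voxel, REAL(origin), REAL(src),
                    REAL(dst));
}

// One ray per detector pixel center from each source; detector pixels are
// indexed u along x and v along y, pixel (1,1) centered at
// (pitch/2, pitch/2, z_det) in world coordinates.
// [[Rcpp::export]]
NumericVector siddon_project_cpp(NumericVector mu, double voxel,
                                 NumericVector origin,
                                 NumericMatrix sources, double pitch,
                                 int n_u, int n_v, double z_det) {
  IntegerVector d = mu.attr("dim");
  int dims[3] = {d[0], d[1], d[2]};
  int ns = sources.nrow();
  NumericVector out(Dimension(n_u, n_v, ns));
  double *po = REAL(out);
  const double *pm = REAL(mu);
  const double *porig = REAL(origin);
  for (int s = 0; s < ns; ++s) {
    double src[3] = {sources(s, 0), sources(s, 1), sources(s, 2)};
    for (int v = 0; v < n_v; ++v) {
      double dst[3];
      dst[1] = (v + 0.5) * pitch;
      dst[2] = z_det;
      for (int u = 0; u < n_u; ++u) {
        dst[0] = (u + 0.5) * pitch;
        po[u + (R_xlen_t)n_u * (v + (R_xlen_t)n_v * s)] =
            siddon_one(pm, dims, voxel, porig, src, dst);
      }
    }
  }
  return out;
}
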