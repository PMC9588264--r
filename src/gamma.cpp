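#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Trilinear interpolation of v (nx*ny*nz, column-major) at fractional voxel
// coordinates (fx, fy, fz); coordinates clamped to the voxel-centre hull.
static inline double trilin(const double *v, int nx, int ny, int nz,
                            double fx, double fy, double fz) {
  if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
  if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
  if (fz < 0) fz = 0; if (fz > nz - 1) fz = nz - 1;
  int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double wx = fx - x0, wy = fy - y0, wz = fz - z0;
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  const double *p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - wx) + p[sx] * wx;
  double c10 = p[sy] * (1 - wx) + p[sy + sx] * wx;
  double c01 = p[sz] * (1 - wx) + p[sz + sx] * wx;
  double c11 = p[sz + sy] * (1 - wx) + p[sz + sy + sx] * wx;
  double c0 = c00 * (1 - wy) + c10 * wy;
  double c1 = c01 * (1 - wy) + c11 * wy;
  return c0 * (1 - wz) + c1 * wz;
}

// 3D gamma index per reference voxel:
//   gamma(r) = min_e sqrt(|e-r|^2/dr^2 + (D_eval(e)-D_ref(r))^2/dd_abs^2)
// over evaluation positions e on a subsampled lattice (offsets, mm) within a
// spherical search cap, evaluated by trilinear interpolation. Offsets must be
// sorted by ascending distance; the loop terminates early once the distance
// term alone exceeds the current best gamma^2.
// dd_abs: absolute dose tolerance (same units as dose). For local gamma pass
// local = true, then dd_abs is the relative tolerance (fraction) applied to
// the reference voxel dose.
// [[Rcpp::export]]
NumericVector cpp_gamma_map(NumericVector ref, NumericVector eval,
                            IntegerVector dim, NumericVector spacing,
                            NumericMatrix offsets, NumericVector off_dist2,
                            double dr_mm, double dd_abs, bool local) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dr2 = dr_mm * dr_mm;
  const int noff = offsets.nrow();
  const double *rv = REAL(ref), *ev = REAL(eval);
  NumericVector gam((size_t)nx * ny * nz);

  // pre-scale offsets to fractional voxel units
  std::vector<double> ox(noff), oy(noff), oz(noff), od(noff);
  for (int m = 0; m < noff; ++m) {
    ox[m] = offsets(m, 0) / spacing[0];
    oy[m] = offsets(m, 1) / spacing[1];
    oz[m] = offsets(m, 2) / spacing[2];
    od[m] = off_dist2[m] / dr2;
  }

  size_t idx = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x, ++idx) {
        const double dref = rv[idx];
        double tol = local ? std::abs(dref) * dd_abs : dd_abs;
        if (tol <= 0) tol = 1e-300;
        double dd0 = (ev[idx] - dref) / tol;
        double best = dd0 * dd0;
        for (int m = 0; m < noff; ++m) {
          if (od[m] >= best) break; // sorted: no further point can improve
          double de = trilin(ev, nx, ny, nz, x + ox[m], y + oy[m], z + oz[m]);
          double dd = (de - dref) / tol;
          double g2 = od[m] + dd * dd;
          if (g2 < best) best = g2;
        }
        gam[idx] = std::sqrt(best);
      }
    }
  }
  return gam;
}
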