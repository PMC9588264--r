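#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deposit pencil-beam dose for one beam travelling along +/-x.
// amp(ix, ray) is the per-voxel depth-dose amplitude along x for each ray;
// it is spread over (y, z) with a separable Gaussian of width sigma(ix) mm,
// normalised so the discrete lateral kernel sums to 1 (exact linearity).
// iy0/iz0 are 0-based voxel indices of the ray axes.
// [[Rcpp::export]]
NumericVector cpp_add_beam_dose(NumericVector dose, IntegerVector dim,
                                NumericVector spacing, IntegerVector iy0,
                                IntegerVector iz0, NumericMatrix amp,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dy = spacing[1], dz = spacing[2];
  const int nray = iy0.size();
  NumericVector out = clone(dose);

  // Precompute per-ix lateral kernels (shared by all rays)
  std::vector<std::vector<double>> ky(nx), kz(nx);
  std::vector<int> ry(nx), rz(nx);
  for (int ix = 0; ix < nx; ++ix) {
    double s = sigma[ix];
    if (s < 1e-6) s = 1e-6;
    ry[ix] = (int)std::ceil(3.0 * s / dy);
    rz[ix] = (int)std::ceil(3.0 * s / dz);
    ky[ix].resize(2 * ry[ix] + 1);
    kz[ix].resize(2 * rz[ix] + 1);
    double sy = 0.0, sz = 0.0;
    for (int j = -ry[ix]; j <= ry[ix]; ++j) {
      double w = std::exp(-0.5 * (j * dy) * (j * dy) / (s * s));
      ky[ix][j + ry[ix]] = w;
      sy += w;
    }
    for (int j = -rz[ix]; j <= rz[ix]; ++j) {
      double w = std::exp(-0.5 * (j * dz) * (j * dz) / (s * s));
      kz[ix][j + rz[ix]] = w;
      sz += w;
    }
    for (auto &w : ky[ix]) w /= sy;
    for (auto &w : kz[ix]) w /= sz;
  }

  for (int r = 0; r < nray; ++r) {
    const int y0 = iy0[r], z0 = iz0[r];
    for (int ix = 0; ix < nx; ++ix) {
      const double a = amp(ix, r);
      if (a <= 1e-12) continue;
      const int Ry = ry[ix], Rz = rz[ix];
      for (int jz = std::max(0, z0 - Rz); jz <= std::min(nz - 1, z0 + Rz); ++jz) {
        const double wz = kz[ix][jz - z0 + Rz] * a;
        double *col = REAL(out) + (size_t)ix + (size_t)nx * ny * jz;
        for (int jy = std::max(0, y0 - Ry); jy <= std::min(ny - 1, y0 + Ry); ++jy) {
          col[(size_t)nx * jy] += ky[ix][jy - y0 + Ry] * wz;
        }
      }
    }
  }
  return out;
}
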