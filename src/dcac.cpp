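#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Arrays arrive as R column-major vectors with dims (nz, ny, nx):
// linear index = z + nz * (y + ny * x).

// Exact windowed median with replicated-edge borders. Window size per axis
// is 2*r+1, always odd, so the median is the middle order statistic.
// [[Rcpp::export]]
NumericVector median_filter_cpp(NumericVector img, IntegerVector dims,
                                IntegerVector radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int rz = radius[0], ry = radius[1], rx = radius[2];
  NumericVector out(img.size());
  const int wlen = (2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1);
  std::vector<double> win(wlen);
  const int mid = wlen / 2;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int k = 0;
        for (int dx = -rx; dx <= rx; ++dx) {
          int xx = std::min(std::max(x + dx, 0), nx - 1);
          for (int dy = -ry; dy <= ry; ++dy) {
            int yy = std::min(std::max(y + dy, 0), ny - 1);
            for (int dz = -rz; dz <= rz; ++dz) {
              int zz = std::min(std::max(z + dz, 0), nz - 1);
              win[k++] = img[zz + nz * (yy + ny * xx)];
            }
          }
        }
        std::nth_element(win.begin(), win.begin() + mid, win.end());
        out[z + nz * (y + ny * x)] = win[mid];
      }
    }
  }
  return out;
}

// One or more Gauss-Seidel sweeps of the u-subproblem. Each voxel update
// averages the six face neighbours (replicated at the boundary) plus the
// divergence source zeta, minus (lambda/mu) * e_r, then clamps to [0, 1].
// Voxels are visited in lexicographic (z, y, x) order — z slowest — and
// neighbour reads see values already updated within the current sweep.
// [[Rcpp::export]]
NumericVector gauss_seidel_cpp(NumericVector u, NumericVector zeta,
                               NumericVector er, double lam_over_mu,
                               int sweeps, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector v = clone(u);
  for (int s = 0; s < sweeps; ++s) {
    for (int z = 0; z < nz; ++z) {
      const int zm = (z > 0) ? z - 1 : 0;
      const int zp = (z < nz - 1) ? z + 1 : nz - 1;
      for (int y = 0; y < ny; ++y) {
        const int ym = (y > 0) ? y - 1 : 0;
        const int yp = (y < ny - 1) ? y + 1 : ny - 1;
        for (int x = 0; x < nx; ++x) {
          const int xm = (x > 0) ? x - 1 : 0;
          const int xp = (x < nx - 1) ? x + 1 : nx - 1;
          const int i = z + nz * (y + ny * x);
          double phi = (v[zm + nz * (y + ny * x)] + v[zp + nz * (y + ny * x)]
                      + v[z + nz * (ym + ny * x)] + v[z + nz * (yp + ny * x)]
                      + v[z + nz * (y + ny * xm)] + v[z + nz * (y + ny * xp)]
                      + zeta[i] - lam_over_mu * er[i]) / 6.0;
          v[i] = std::max(0.0, std::min(1.0, phi));
        }
      }
    }
  }
  return v;
}
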