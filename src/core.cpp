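#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-major linear index for a 3-D grid.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable Gaussian convolution of a 3-D array with per-axis sigma in
// voxel units. Edge handling replicates the border voxel, so an interior
// impulse keeps its mass exactly (kernels are normalised).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector arr, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> src(arr.begin(), arr.end());
  std::vector<double> dst(src.size());
  const int n[3] = {nx, ny, nz};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
      sum += ker[t + r];
    }
    for (double& w : ker) w /= sum;

    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = i, jj = j, kk = k;
            if (ax == 0) ii = clampi(i + t, 0, nx - 1);
            else if (ax == 1) jj = clampi(j + t, 0, ny - 1);
            else kk = clampi(k + t, 0, nz - 1);
            acc += ker[t + r] * src[lin(ii, jj, kk, nx, ny)];
          }
          dst[lin(i, j, k, nx, ny)] = acc;
        }
      }
    }
    std::swap(src, dst);
    (void)n;
  }
  NumericVector out(src.begin(), src.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear interpolation at continuous 0-based voxel coordinates.
// pts is n x 3. Outside the grid: nearest-edge clamp when clamp = true,
// otherwise the constant `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dim,
                            NumericMatrix pts, bool clamp, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!clamp && (x < 0 || y < 0 || z < 0 ||
                   x > nx - 1 || y > ny - 1 || z > nz - 1)) {
      out[p] = fill;
      continue;
    }
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = arr[lin(i0, j0, k0, nx, ny)];
    double c100 = arr[lin(i0 + 1, j0, k0, nx, ny)];
    double c010 = arr[lin(i0, j0 + 1, k0, nx, ny)];
    double c110 = arr[lin(i0 + 1, j0 + 1, k0, nx, ny)];
    double c001 = arr[lin(i0, j0, k0 + 1, nx, ny)];
    double c101 = arr[lin(i0 + 1, j0, k0 + 1, nx, ny)];
    double c011 = arr[lin(i0, j0 + 1, k0 + 1, nx, ny)];
    double c111 = arr[lin(i0 + 1, j0 + 1, k0 + 1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// 26-connected component of `mask` containing the seed voxel (0-based).
// [[Rcpp::export]]
LogicalVector cpp_flood26(LogicalVector mask, IntegerVector dim,
                          IntegerVector seed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  R_xlen_t s = lin(seed[0], seed[1], seed[2], nx, ny);
  if (!mask[s]) return out;
  std::vector<R_xlen_t> stack;
  stack.push_back(s);
  out[s] = true;
  while (!stack.empty()) {
    R_xlen_t cur = stack.back();
    stack.pop_back();
    int i = (int)(cur % nx);
    int j = (int)((cur / nx) % ny);
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          R_xlen_t q = lin(ii, jj, kk, nx, ny);
          if (mask[q] && !out[q]) {
            out[q] = true;
            stack.push_back(q);
          }
        }
  }
  out.attr("dim") = dim;
  return out;
}
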