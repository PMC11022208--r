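#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// dim = (nz, ny, nx); column-major, z fastest.

static inline R_xlen_t lin(int iz, int iy, int ix, int nz, int ny) {
  return (R_xlen_t)iz + (R_xlen_t)nz * ((R_xlen_t)iy + (R_xlen_t)ny * (R_xlen_t)ix);
}

// symmetric (half-sample) reflection: ..., 1, 0 | 0, 1, ..., n-1 | n-1, n-2, ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return i < n ? i : period - 1 - i;
}

static void conv1d_axis(const double* src, double* dst, int nz, int ny, int nx,
                        int axis, const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  int n[3] = {nz, ny, nx};
  int na = n[axis];
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        int idx[3] = {iz, iy, ix};
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int jdx[3] = {iz, iy, ix};
          jdx[axis] = reflect_idx(idx[axis] + j, na);
          acc += k[j + r] * src[lin(jdx[0], jdx[1], jdx[2], nz, ny)];
        }
        dst[lin(iz, iy, ix, nz, ny)] = acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, double sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int j = -r; j <= r; ++j) {
    k[j + r] = std::exp(-0.5 * j * j / (sigma * sigma));
    s += k[j + r];
  }
  for (auto& w : k) w /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(nvox);
  conv1d_axis(a.data(), b.data(), nz, ny, nx, 0, k);
  conv1d_axis(b.data(), a.data(), nz, ny, nx, 1, k);
  conv1d_axis(a.data(), b.data(), nz, ny, nx, 2, k);
  NumericVector out(nvox);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// Binary box dilation: separable running max with half-widths (rz, ry, rx).
static void max1d_axis(const int* src, int* dst, int nz, int ny, int nx,
                       int axis, int r) {
  int n[3] = {nz, ny, nx};
  int na = n[axis];
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        int idx[3] = {iz, iy, ix};
        int m = 0;
        int lo = std::max(0, idx[axis] - r), hi = std::min(na - 1, idx[axis] + r);
        for (int j = lo; j <= hi && !m; ++j) {
          int jdx[3] = {iz, iy, ix};
          jdx[axis] = j;
          m = src[lin(jdx[0], jdx[1], jdx[2], nz, ny)];
        }
        dst[lin(iz, iy, ix, nz, ny)] = m;
      }
}

// [[Rcpp::export]]
IntegerVector cpp_box_dilate(IntegerVector mask, IntegerVector dim,
                             int rz, int ry, int rx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  std::vector<int> a(mask.begin(), mask.end()), b(nvox);
  max1d_axis(a.data(), b.data(), nz, ny, nx, 0, rz);
  max1d_axis(b.data(), a.data(), nz, ny, nx, 1, ry);
  max1d_axis(a.data(), b.data(), nz, ny, nx, 2, rx);
  IntegerVector out(nvox);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// 6-connected component labelling of a binary mask; labels 1..k, 0 background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(nvox);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int iz = (int)(cur % nz);
      int iy = (int)((cur / nz) % ny);
      int ix = (int)(cur / ((R_xlen_t)nz * ny));
      const int dz[6] = {-1,1,0,0,0,0}, dy[6] = {0,0,-1,1,0,0}, dx[6] = {0,0,0,0,-1,1};
      for (int d = 0; d < 6; ++d) {
        int z = iz + dz[d], y = iy + dy[d], x = ix + dx[d];
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        R_xlen_t q = lin(z, y, x, nz, ny);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}
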