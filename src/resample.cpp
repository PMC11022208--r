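#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Arrays are column-major with dim = (nz, ny, nx); voxel (iz,iy,ix) sits at
// linear index iz + nz*(iy + ny*ix).  Voxel centers are cell-centered:
// physical position = origin + (index + 0.5) * spacing.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline R_xlen_t lin(int iz, int iy, int ix, int nz, int ny) {
  return (R_xlen_t)iz + (R_xlen_t)nz * ((R_xlen_t)iy + (R_xlen_t)ny * (R_xlen_t)ix);
}

static double sample_trilinear(const double* v, int nz, int ny, int nx,
                               double uz, double uy, double ux) {
  uz = clampd(uz, 0.0, nz - 1.0);
  uy = clampd(uy, 0.0, ny - 1.0);
  ux = clampd(ux, 0.0, nx - 1.0);
  int z0 = (int)std::floor(uz), y0 = (int)std::floor(uy), x0 = (int)std::floor(ux);
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  // degenerate axes (n == 1) handled by zero fraction
  double fz = nz > 1 ? uz - z0 : 0.0;
  double fy = ny > 1 ? uy - y0 : 0.0;
  double fx = nx > 1 ? ux - x0 : 0.0;
  int z1 = nz > 1 ? z0 + 1 : z0, y1 = ny > 1 ? y0 + 1 : y0, x1 = nx > 1 ? x0 + 1 : x0;
  double c000 = v[lin(z0,y0,x0,nz,ny)], c001 = v[lin(z0,y0,x1,nz,ny)];
  double c010 = v[lin(z0,y1,x0,nz,ny)], c011 = v[lin(z0,y1,x1,nz,ny)];
  double c100 = v[lin(z1,y0,x0,nz,ny)], c101 = v[lin(z1,y0,x1,nz,ny)];
  double c110 = v[lin(z1,y1,x0,nz,ny)], c111 = v[lin(z1,y1,x1,nz,ny)];
  double c00 = c000 * (1-fx) + c001 * fx;
  double c01 = c010 * (1-fx) + c011 * fx;
  double c10 = c100 * (1-fx) + c101 * fx;
  double c11 = c110 * (1-fx) + c111 * fx;
  double c0 = c00 * (1-fy) + c01 * fy;
  double c1 = c10 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim_in,
                           IntegerVector dim_out, bool nearest) {
  int nz = dim_in[0], ny = dim_in[1], nx = dim_in[2];
  int mz = dim_out[0], my = dim_out[1], mx = dim_out[2];
  NumericVector out((R_xlen_t)mz * my * mx);
  const double* v = vol.begin();
  double rz = (double)nz / mz, ry = (double)ny / my, rx = (double)nx / mx;
  for (int ix = 0; ix < mx; ++ix) {
    double ux = (ix + 0.5) * rx - 0.5;
    for (int iy = 0; iy < my; ++iy) {
      double uy = (iy + 0.5) * ry - 0.5;
      for (int iz = 0; iz < mz; ++iz) {
        double uz = (iz + 0.5) * rz - 0.5;
        double val;
        if (nearest) {
          int z = (int)clampd(std::floor(uz + 0.5), 0, nz - 1);
          int y = (int)clampd(std::floor(uy + 0.5), 0, ny - 1);
          int x = (int)clampd(std::floor(ux + 0.5), 0, nx - 1);
          val = v[lin(z,y,x,nz,ny)];
        } else {
          val = sample_trilinear(v, nz, ny, nx, uz, uy, ux);
        }
        out[lin(iz,iy,ix,mz,my)] = val;
      }
    }
  }
  return out;
}

// Sample vol at source index M %*% p + t for every output voxel p (indices in
// (z,y,x) order).  Points mapping outside the input grid get `outside`.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector dim,
                                NumericMatrix M, NumericVector t,
                                bool nearest, double outside) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out((R_xlen_t)nz * ny * nx);
  const double* v = vol.begin();
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int iz = 0; iz < nz; ++iz) {
        double uz = M(0,0)*iz + M(0,1)*iy + M(0,2)*ix + t[0];
        double uy = M(1,0)*iz + M(1,1)*iy + M(1,2)*ix + t[1];
        double ux = M(2,0)*iz + M(2,1)*iy + M(2,2)*ix + t[2];
        double val;
        if (uz < -0.5 || uz > nz - 0.5 || uy < -0.5 || uy > ny - 0.5 ||
            ux < -0.5 || ux > nx - 0.5) {
          val = outside;
        } else if (nearest) {
          int z = (int)clampd(std::floor(uz + 0.5), 0, nz - 1);
          int y = (int)clampd(std::floor(uy + 0.5), 0, ny - 1);
          int x = (int)clampd(std::floor(ux + 0.5), 0, nx - 1);
          val = v[lin(z,y,x,nz,ny)];
        } else {
          val = sample_trilinear(v, nz, ny, nx, uz, uy, ux);
        }
        out[lin(iz,iy,ix,nz,ny)] = val;
      }
    }
  }
  return out;
}
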