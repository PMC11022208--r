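#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Iso-surface extraction by a 6-tetrahedra decomposition of each grid cell
// (marching tetrahedra).  Unlike the classic 256-case cube table, the
// tetrahedral cases are unambiguous, so the extracted surface of any field
// that does not touch the volume boundary is a closed 2-manifold by
// construction.  Vertices are welded through a grid-edge hash map so shared
// edges index shared vertices.
//
// dim = (nz, ny, nx), column-major, z fastest.  Grid points are voxel
// centers: position = origin + (index + 0.5) * spacing, coordinates (x,y,z).

static inline R_xlen_t lin(int iz, int iy, int ix, int nz, int ny) {
  return (R_xlen_t)iz + (R_xlen_t)nz * ((R_xlen_t)iy + (R_xlen_t)ny * (R_xlen_t)ix);
}

struct Vec3 { double x, y, z; };

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector vol, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             double iso) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  const double* v = vol.begin();

  // nudge values lying exactly on the iso level so every crossing is strict
  double vmax = 0.0;
  for (R_xlen_t i = 0; i < vol.size(); ++i) vmax = std::max(vmax, std::fabs(v[i]));
  double eps = 1e-7 * std::max(vmax, 1.0);

  auto val = [&](R_xlen_t id) {
    double x = v[id];
    return x == iso ? x + eps : x;
  };
  auto pos = [&](R_xlen_t id) {
    int iz = (int)(id % nz);
    int iy = (int)((id / nz) % ny);
    int ix = (int)(id / ((R_xlen_t)nz * ny));
    Vec3 p = {ox + (ix + 0.5) * sx, oy + (iy + 0.5) * sy, oz + (iz + 0.5) * sz};
    return p;
  };

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto edge_point = [&](R_xlen_t a, R_xlen_t b) {
    R_xlen_t lo = std::min(a, b), hi = std::max(a, b);
    uint64_t key = (uint64_t)lo * (uint64_t)(nz * (R_xlen_t)ny * nx) + (uint64_t)hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = val(a), vb = val(b);
    double t = (iso - va) / (vb - va);
    Vec3 pa = pos(a), pb = pos(b);
    vx.push_back(pa.x + t * (pb.x - pa.x));
    vy.push_back(pa.y + t * (pb.y - pa.y));
    vz.push_back(pa.z + t * (pb.z - pa.z));
    int idx = (int)vx.size() - 1;
    edge_vertex[key] = idx;
    return idx;
  };

  // orientation fix: outward normal points from the inside (> iso) region out
  auto emit = [&](int a, int b, int c, const Vec3& out_dir) {
    double e1x = vx[b]-vx[a], e1y = vy[b]-vy[a], e1z = vz[b]-vz[a];
    double e2x = vx[c]-vx[a], e2y = vy[c]-vy[a], e2z = vz[c]-vz[a];
    double nxn = e1y*e2z - e1z*e2y;
    double nyn = e1z*e2x - e1x*e2z;
    double nzn = e1x*e2y - e1y*e2x;
    double d = nxn*out_dir.x + nyn*out_dir.y + nzn*out_dir.z;
    if (d >= 0) { f0.push_back(a); f1.push_back(b); f2.push_back(c); }
    else        { f0.push_back(a); f1.push_back(c); f2.push_back(b); }
  };

  // six tetrahedra sharing the main diagonal (corner bit order x,y,z)
  static const int tets[6][4] = {
    {0,5,1,7}, {0,1,3,7}, {0,3,2,7}, {0,2,6,7}, {0,6,4,7}, {0,4,5,7}
  };

  R_xlen_t corner_off[8];
  for (int k = 0; k < 8; ++k)
    corner_off[k] = lin(((k>>2)&1), ((k>>1)&1), (k&1), nz, ny);

  for (int ix = 0; ix < nx - 1; ++ix)
    for (int iy = 0; iy < ny - 1; ++iy)
      for (int iz = 0; iz < nz - 1; ++iz) {
        R_xlen_t base = lin(iz, iy, ix, nz, ny);
        R_xlen_t cid[8];
        double cv[8];
        bool any_in = false, any_out = false;
        for (int k = 0; k < 8; ++k) {
          cid[k] = base + corner_off[k];
          cv[k] = val(cid[k]);
          (cv[k] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int tt = 0; tt < 6; ++tt) {
          R_xlen_t tid[4];
          double tv[4];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            tid[k] = cid[tets[tt][k]];
            tv[k] = cv[tets[tt][k]];
            if (tv[k] > iso) in[nin++] = k; else out[nout++] = k;
          }
          if (nin == 0 || nin == 4) continue;
          Vec3 ci = {0,0,0}, co = {0,0,0};
          for (int k = 0; k < nin; ++k) {
            Vec3 p = pos(tid[in[k]]);
            ci.x += p.x/nin; ci.y += p.y/nin; ci.z += p.z/nin;
          }
          for (int k = 0; k < nout; ++k) {
            Vec3 p = pos(tid[out[k]]);
            co.x += p.x/nout; co.y += p.y/nout; co.z += p.z/nout;
          }
          Vec3 od = {co.x - ci.x, co.y - ci.y, co.z - ci.z};
          if (nin == 1) {
            int a = edge_point(tid[in[0]], tid[out[0]]);
            int b = edge_point(tid[in[0]], tid[out[1]]);
            int c = edge_point(tid[in[0]], tid[out[2]]);
            emit(a, b, c, od);
          } else if (nin == 3) {
            int a = edge_point(tid[in[0]], tid[out[0]]);
            int b = edge_point(tid[in[1]], tid[out[0]]);
            int c = edge_point(tid[in[2]], tid[out[0]]);
            emit(a, b, c, od);
          } else { // 2 in, 2 out -> quad
            int a = edge_point(tid[in[0]], tid[out[0]]);
            int b = edge_point(tid[in[0]], tid[out[1]]);
            int c = edge_point(tid[in[1]], tid[out[1]]);
            int d = edge_point(tid[in[1]], tid[out[0]]);
            emit(a, b, c, od);
            emit(a, c, d, od);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) { Fm(i,0) = f0[i]+1; Fm(i,1) = f1[i]+1; Fm(i,2) = f2[i]+1; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
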