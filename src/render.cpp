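#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Software ray caster with Phong shading for endoscopy-style interior views.
// Median-split BVH over triangles; Moeller-Trumbore intersection.

struct V3 {
  double x, y, z;
  V3 operator+(const V3& o) const { return {x+o.x, y+o.y, z+o.z}; }
  V3 operator-(const V3& o) const { return {x-o.x, y-o.y, z-o.z}; }
  V3 operator*(double s) const { return {x*s, y*s, z*s}; }
};
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3& a) { double n = norm(a); return n > 0 ? a * (1.0/n) : a; }

struct BVHNode {
  double bmin[3], bmax[3];
  int left = -1, right = -1, start = 0, count = 0; // leaf iff count > 0
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> tri;           // triangle order
  const double* Vx; const int* Fx; int nV, nF;
  std::vector<V3> cent;

  void tri_bounds(int t, double* lo, double* hi) const {
    for (int a = 0; a < 3; ++a) { lo[a] = std::numeric_limits<double>::infinity(); hi[a] = -lo[a]; }
    for (int k = 0; k < 3; ++k) {
      int vi = Fx[t + (R_xlen_t)nF * k] - 1;
      double p[3] = {Vx[vi], Vx[vi + (R_xlen_t)nV], Vx[vi + 2*(R_xlen_t)nV]};
      for (int a = 0; a < 3; ++a) { lo[a] = std::min(lo[a], p[a]); hi[a] = std::max(hi[a], p[a]); }
    }
  }

  int build(int lo, int hi) {
    BVHNode nd;
    for (int a = 0; a < 3; ++a) { nd.bmin[a] = std::numeric_limits<double>::infinity(); nd.bmax[a] = -nd.bmin[a]; }
    for (int i = lo; i < hi; ++i) {
      double tlo[3], thi[3];
      tri_bounds(tri[i], tlo, thi);
      for (int a = 0; a < 3; ++a) { nd.bmin[a] = std::min(nd.bmin[a], tlo[a]); nd.bmax[a] = std::max(nd.bmax[a], thi[a]); }
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= 4) {
      nodes[id].start = lo; nodes[id].count = hi - lo;
      return id;
    }
    int axis = 0;
    double ext[3] = {nd.bmax[0]-nd.bmin[0], nd.bmax[1]-nd.bmin[1], nd.bmax[2]-nd.bmin[2]};
    if (ext[1] > ext[axis]) axis = 1;
    if (ext[2] > ext[axis]) axis = 2;
    int mid = (lo + hi) / 2;
    std::nth_element(tri.begin()+lo, tri.begin()+mid, tri.begin()+hi, [&](int a, int b) {
      double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
      double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
      return ca < cb;
    });
    int l = build(lo, mid), r = build(mid, hi);
    nodes[id].left = l; nodes[id].right = r; nodes[id].count = 0;
    return id;
  }

  void init(const double* V, const int* F, int nv, int nf) {
    Vx = V; Fx = F; nV = nv; nF = nf;
    tri.resize(nf);
    cent.resize(nf);
    for (int t = 0; t < nf; ++t) {
      tri[t] = t;
      V3 c = {0,0,0};
      for (int k = 0; k < 3; ++k) {
        int vi = F[t + (R_xlen_t)nf * k] - 1;
        c = c + V3{V[vi], V[vi + (R_xlen_t)nv], V[vi + 2*(R_xlen_t)nv]} * (1.0/3);
      }
      cent[t] = c;
    }
    nodes.reserve(2 * nf);
    build(0, nf);
  }

  static bool hit_box(const V3& o, const V3& inv, const double* bmin, const double* bmax, double tmax) {
    double t0 = 0.0, t1 = tmax;
    const double od[3] = {o.x, o.y, o.z}, iv[3] = {inv.x, inv.y, inv.z};
    for (int a = 0; a < 3; ++a) {
      double ta = (bmin[a] - od[a]) * iv[a];
      double tb = (bmax[a] - od[a]) * iv[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      if (t0 > t1) return false;
    }
    return true;
  }

  bool tri_hit(int t, const V3& o, const V3& d, double& tt, double& u, double& v) const {
    int i0 = Fx[t] - 1, i1 = Fx[t + (R_xlen_t)nF] - 1, i2 = Fx[t + 2*(R_xlen_t)nF] - 1;
    V3 p0 = {Vx[i0], Vx[i0 + (R_xlen_t)nV], Vx[i0 + 2*(R_xlen_t)nV]};
    V3 p1 = {Vx[i1], Vx[i1 + (R_xlen_t)nV], Vx[i1 + 2*(R_xlen_t)nV]};
    V3 p2 = {Vx[i2], Vx[i2 + (R_xlen_t)nV], Vx[i2 + 2*(R_xlen_t)nV]};
    V3 e1 = p1 - p0, e2 = p2 - p0;
    V3 pv = cross(d, e2);
    double det = dot(e1, pv);
    if (std::fabs(det) < 1e-12) return false;
    double inv = 1.0 / det;
    V3 tv = o - p0;
    u = dot(tv, pv) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) return false;
    V3 qv = cross(tv, e1);
    v = dot(d, qv) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) return false;
    tt = dot(e2, qv) * inv;
    return tt > 1e-9;
  }

  // nearest hit; returns face index or -1
  int trace(const V3& o, const V3& d, double& best_t, double& bu, double& bv) const {
    V3 inv = {1.0/d.x, 1.0/d.y, 1.0/d.z};
    best_t = std::numeric_limits<double>::infinity();
    int best = -1;
    int stack[128]; int sp = 0;
    stack[sp++] = 0;
    while (sp) {
      const BVHNode& nd = nodes[stack[--sp]];
      if (!hit_box(o, inv, nd.bmin, nd.bmax, best_t)) continue;
      if (nd.count > 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          double tt, u, v;
          if (tri_hit(tri[i], o, d, tt, u, v) && tt < best_t) {
            best_t = tt; best = tri[i]; bu = u; bv = v;
          }
        }
      } else {
        stack[sp++] = nd.left;
        stack[sp++] = nd.right;
      }
    }
    return best;
  }
};

// [[Rcpp::export]]
NumericVector cpp_render(NumericMatrix Vm, IntegerMatrix Fm,
                         NumericVector cam_pos, NumericVector view_dir,
                         NumericVector up_vec, double vfov_deg,
                         int width, int height, List cfg) {
  int nv = Vm.nrow(), nf = Fm.nrow();
  BVH bvh;
  bvh.init(Vm.begin(), Fm.begin(), nv, nf);

  double ambient  = as<double>(cfg["ambient"]);
  double diffuse  = as<double>(cfg["diffuse"]);
  double specular = as<double>(cfg["specular"]);
  double spec_exp = as<double>(cfg["specular_exponent"]);
  bool headlight  = as<bool>(cfg["headlight"]);
  bool falloff    = as<bool>(cfg["falloff"]);
  double falloff_ref = as<double>(cfg["falloff_ref_mm"]);
  double light_off   = as<double>(cfg["headlight_offset_mm"]);
  bool render_edges  = as<bool>(cfg["render_edges"]);
  double edge_frac   = as<double>(cfg["edge_fraction"]);
  NumericVector base = cfg["base_color"];
  NumericVector bg   = cfg["background"];
  NumericVector ldir = cfg["light_dir"];     // unit vector pointing toward the light
  NumericMatrix pal  = cfg["edge_palette"];  // k x 3

  V3 O = {cam_pos[0], cam_pos[1], cam_pos[2]};
  V3 D = unit({view_dir[0], view_dir[1], view_dir[2]});
  V3 U0 = {up_vec[0], up_vec[1], up_vec[2]};
  V3 R = unit(cross(D, U0));
  V3 U = cross(R, D);
  double tanv = std::tan(vfov_deg * M_PI / 360.0);
  double aspect = (double)width / height;
  V3 lpos = O - D * light_off;
  V3 ldirv = unit({ldir[0], ldir[1], ldir[2]});

  NumericVector img((R_xlen_t)height * width * 3);
  for (int row = 0; row < height; ++row) {
    double py = (1.0 - 2.0 * (row + 0.5) / height) * tanv;
    for (int col = 0; col < width; ++col) {
      double px = (2.0 * (col + 0.5) / width - 1.0) * tanv * aspect;
      V3 d = unit(D + R * px + U * py);
      double t, u, v;
      int face = bvh.trace(O, d, t, u, v);
      double rgb[3];
      if (face < 0) {
        rgb[0] = bg[0]; rgb[1] = bg[1]; rgb[2] = bg[2];
      } else {
        int i0 = Fm(face,0)-1, i1 = Fm(face,1)-1, i2 = Fm(face,2)-1;
        V3 p0 = {Vm(i0,0), Vm(i0,1), Vm(i0,2)};
        V3 p1 = {Vm(i1,0), Vm(i1,1), Vm(i1,2)};
        V3 p2 = {Vm(i2,0), Vm(i2,1), Vm(i2,2)};
        V3 hit = O + d * t;
        V3 n = unit(cross(p1 - p0, p2 - p0));
        if (dot(n, d) > 0) n = n * -1.0;  // face the viewer (interior walls)
        V3 l; double att = 1.0;
        if (headlight) {
          V3 tolight = lpos - hit;
          double dist = norm(tolight);
          l = tolight * (1.0 / std::max(dist, 1e-9));
          if (falloff) att = std::min(1.0, (falloff_ref * falloff_ref) / std::max(dist * dist, 1e-9));
        } else {
          l = ldirv;
        }
        double ndl = std::max(0.0, dot(n, l));
        V3 refl = n * (2.0 * dot(n, l)) - l;
        double rdv = std::max(0.0, dot(refl, d * -1.0));
        double spec = specular > 0 ? specular * std::pow(rdv, spec_exp) * att : 0.0;
        for (int c = 0; c < 3; ++c) {
          double val = ambient * base[c] + diffuse * base[c] * ndl * att + spec;
          rgb[c] = std::min(1.0, std::max(0.0, val));
        }
        if (render_edges && pal.nrow() > 0) {
          double w = 1.0 - u - v;
          int eidx; double m;
          // barycentric of the opposite vertex ~ 0 near an edge
          if (v <= w && v <= u)      { eidx = 0; m = v; }  // edge (v0,v1)
          else if (w <= u)           { eidx = 1; m = w; }  // edge (v1,v2)
          else                       { eidx = 2; m = u; }  // edge (v2,v0)
          if (m < edge_frac) {
            int k = (face * 3 + eidx) % pal.nrow();
            rgb[0] = pal(k,0); rgb[1] = pal(k,1); rgb[2] = pal(k,2);
          }
        }
      }
      for (int c = 0; c < 3; ++c)
        img[(R_xlen_t)row + (R_xlen_t)height * (col + (R_xlen_t)width * c)] = rgb[c];
    }
  }
  img.attr("dim") = IntegerVector::create(height, width, 3);
  return img;
}
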