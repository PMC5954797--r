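// Geometry core: ray-cast voxelization with partial volume, inside tests for
// multi-part CSG meshes (part sign +1 solid / -1 cavity), exact closest
// point-to-triangle queries with a uniform-grid accelerator, marching-
// tetrahedra iso-surface extraction, exact Euclidean distance transform,
// connected components, hole filling, and separable 1-D convolution.
// All coordinates are millimetres; grids are column-major (x fastest).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <limits>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 2-D triangle binning for rays parallel to z
// ---------------------------------------------------------------------------

struct XYBins {
  double x0, y0, hx, hy;
  int nx, ny;
  std::vector< std::vector<int> > cells;

  void build(const NumericMatrix& V, const IntegerMatrix& F, int ncell_target) {
    double xmin = INF, xmax = -INF, ymin = INF, ymax = -INF;
    for (int i = 0; i < V.nrow(); ++i) {
      xmin = std::min(xmin, V(i,0)); xmax = std::max(xmax, V(i,0));
      ymin = std::min(ymin, V(i,1)); ymax = std::max(ymax, V(i,1));
    }
    double ex = std::max(xmax - xmin, 1e-9), ey = std::max(ymax - ymin, 1e-9);
    double cell = std::sqrt(ex * ey / std::max(1, ncell_target));
    nx = std::max(1, (int)std::ceil(ex / cell));
    ny = std::max(1, (int)std::ceil(ey / cell));
    nx = std::min(nx, 2048); ny = std::min(ny, 2048);
    x0 = xmin; y0 = ymin; hx = ex / nx; hy = ey / ny;
    cells.assign((size_t)nx * ny, std::vector<int>());
    for (int f = 0; f < F.nrow(); ++f) {
      double txmin = INF, txmax = -INF, tymin = INF, tymax = -INF;
      for (int k = 0; k < 3; ++k) {
        int v = F(f,k);
        txmin = std::min(txmin, V(v,0)); txmax = std::max(txmax, V(v,0));
        tymin = std::min(tymin, V(v,1)); tymax = std::max(tymax, V(v,1));
      }
      int i0 = std::min(nx - 1, std::max(0, (int)std::floor((txmin - x0) / hx)));
      int i1 = std::min(nx - 1, (int)std::floor((txmax - x0) / hx));
      int j0 = std::min(ny - 1, std::max(0, (int)std::floor((tymin - y0) / hy)));
      int j1 = std::min(ny - 1, (int)std::floor((tymax - y0) / hy));
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          cells[(size_t)j * nx + i].push_back(f);
    }
  }

  const std::vector<int>* query(double x, double y) const {
    int i = (int)std::floor((x - x0) / hx);
    int j = (int)std::floor((y - y0) / hy);
    if (i < 0 || i >= nx || j < 0 || j >= ny) return nullptr;
    return &cells[(size_t)j * nx + i];
  }
};

// z crossings of the vertical ray through (x, y); appends (z, face) pairs
static void ray_z_crossings(const NumericMatrix& V, const IntegerMatrix& F,
                            const XYBins& bins, double x, double y,
                            std::vector< std::pair<double,int> >& out) {
  const std::vector<int>* cand = bins.query(x, y);
  if (!cand) return;
  for (int f : *cand) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    double ax = V(a,0) - x, ay = V(a,1) - y;
    double bx = V(b,0) - x, by = V(b,1) - y;
    double cx = V(c,0) - x, cy = V(c,1) - y;
    // signed areas of sub-triangles: (x,y) inside iff all same sign
    double d1 = ax * by - ay * bx;
    double d2 = bx * cy - by * cx;
    double d3 = cx * ay - cy * ax;
    bool pos = (d1 > 0) && (d2 > 0) && (d3 > 0);
    bool neg = (d1 < 0) && (d2 < 0) && (d3 < 0);
    if (!pos && !neg) continue;          // outside or on edge (jittered rays)
    double area = d1 + d2 + d3;
    double z = (d2 * V(a,2) + d3 * V(b,2) + d1 * V(c,2)) / area;
    out.push_back(std::make_pair(z, f));
  }
}

// merge parity crossings of one part into sorted inside-intervals
static void parity_intervals(std::vector<double>& zs,
                             std::vector< std::pair<double,double> >& iv) {
  std::sort(zs.begin(), zs.end());
  size_t n = zs.size() & ~(size_t)1;     // drop an unpaired grazing crossing
  for (size_t k = 0; k + 1 < n; k += 2)
    iv.push_back(std::make_pair(zs[k], zs[k+1]));
}

// union of intervals (in place, sorted by start on return)
static void union_intervals(std::vector< std::pair<double,double> >& iv) {
  if (iv.empty()) return;
  std::sort(iv.begin(), iv.end());
  std::vector< std::pair<double,double> > out;
  out.push_back(iv[0]);
  for (size_t k = 1; k < iv.size(); ++k) {
    if (iv[k].first <= out.back().second)
      out.back().second = std::max(out.back().second, iv[k].second);
    else out.push_back(iv[k]);
  }
  iv.swap(out);
}

// subtract union B from union A (both sorted unions)
static void subtract_intervals(const std::vector< std::pair<double,double> >& A,
                               const std::vector< std::pair<double,double> >& B,
                               std::vector< std::pair<double,double> >& out) {
  for (auto seg : A) {
    double s = seg.first, e = seg.second;
    for (auto b : B) {
      if (b.second <= s || b.first >= e) continue;
      if (b.first > s) out.push_back(std::make_pair(s, b.first));
      s = std::max(s, b.second);
      if (s >= e) break;
    }
    if (s < e) out.push_back(std::make_pair(s, e));
  }
}

// solid z-intervals of the CSG mesh along the ray through (x, y)
static void solid_intervals(const NumericMatrix& V, const IntegerMatrix& F,
                            const IntegerVector& part, const IntegerVector& psign,
                            int nparts, const XYBins& bins, double x, double y,
                            std::vector< std::pair<double,double> >& res) {
  std::vector< std::pair<double,int> > cr;
  ray_z_crossings(V, F, bins, x, y, cr);
  if (cr.empty()) return;
  std::vector< std::vector<double> > by_part(nparts);
  for (auto& p : cr) by_part[part[p.second] - 1].push_back(p.first);
  std::vector< std::pair<double,double> > pos, neg;
  for (int p = 0; p < nparts; ++p) {
    if (by_part[p].empty()) continue;
    if (psign[p] >= 0) parity_intervals(by_part[p], pos);
    else               parity_intervals(by_part[p], neg);
  }
  union_intervals(pos);
  union_intervals(neg);
  if (neg.empty()) { res.swap(pos); return; }
  subtract_intervals(pos, neg, res);
}

// ---------------------------------------------------------------------------
// voxelization with partial volume
// ---------------------------------------------------------------------------

// occupancy fraction per voxel: exact integration along z, ss x ss jittered
// supersampling in-plane
// [[Rcpp::export]]
NumericVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           IntegerVector part, IntegerVector psign,
                           NumericVector origin, NumericVector spacing,
                           IntegerVector dims, int ss) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nparts = psign.size();
  NumericVector occ((R_xlen_t)nx * ny * nz);
  XYBins bins; bins.build(V, F, std::max(64, F.nrow() / 4));
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  double z0 = origin[2];
  double w = 1.0 / (ss * (double)ss);
  std::vector< std::pair<double,double> > iv;
  for (int j = 0; j < ny; ++j) {
    Rcpp::checkUserInterrupt();
    for (int i = 0; i < nx; ++i) {
      for (int a = 0; a < ss; ++a) for (int b = 0; b < ss; ++b) {
        double x = origin[0] + (i + (a + 0.5) / ss) * hx + hx * 1.23456789e-4;
        double y = origin[1] + (j + (b + 0.5) / ss) * hy + hy * 2.34567891e-4;
        iv.clear();
        solid_intervals(V, F, part, psign, nparts, bins, x, y, iv);
        for (auto& seg : iv) {
          int k0 = std::max(0, (int)std::floor((seg.first  - z0) / hz));
          int k1 = std::min(nz - 1, (int)std::floor((seg.second - z0) / hz));
          for (int k = k0; k <= k1; ++k) {
            double za = z0 + k * hz, zb = za + hz;
            double ov = std::min(seg.second, zb) - std::max(seg.first, za);
            if (ov > 0)
              occ[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] += w * ov / hz;
          }
        }
      }
    }
  }
  return occ;
}

// inside-solid test for arbitrary points (CSG parts)
// [[Rcpp::export]]
LogicalVector cpp_inside(NumericMatrix V, IntegerMatrix F,
                         IntegerVector part, IntegerVector psign,
                         NumericMatrix P) {
  int nparts = psign.size();
  XYBins bins; bins.build(V, F, std::max(64, F.nrow() / 4));
  int n = P.nrow();
  LogicalVector res(n);
  std::vector< std::pair<double,double> > iv;
  for (int q = 0; q < n; ++q) {
    iv.clear();
    solid_intervals(V, F, part, psign, nparts, bins,
                    P(q,0) + 7.07106781e-7, P(q,1) + 5.77350269e-7, iv);
    double z = P(q,2);
    bool in = false;
    for (auto& seg : iv) if (z > seg.first && z < seg.second) { in = true; break; }
    res[q] = in;
  }
  return res;
}

// all crossings of an arbitrary ray with the mesh (brute force over faces);
// returns sorted signed parameters t with crossing point = origin + t * dir
// [[Rcpp::export]]
NumericVector cpp_ray_crossings(NumericMatrix V, IntegerMatrix F,
                                NumericVector orig, NumericVector dir) {
  std::vector<double> ts;
  double ox = orig[0], oy = orig[1], oz = orig[2];
  double dx = dir[0], dy = dir[1], dz = dir[2];
  for (int f = 0; f < F.nrow(); ++f) {
    int ia = F(f,0), ib = F(f,1), ic = F(f,2);
    double e1x = V(ib,0)-V(ia,0), e1y = V(ib,1)-V(ia,1), e1z = V(ib,2)-V(ia,2);
    double e2x = V(ic,0)-V(ia,0), e2y = V(ic,1)-V(ia,1), e2z = V(ic,2)-V(ia,2);
    double px = dy*e2z - dz*e2y, py = dz*e2x - dx*e2z, pz = dx*e2y - dy*e2x;
    double det = e1x*px + e1y*py + e1z*pz;
    if (std::fabs(det) < 1e-14) continue;
    double tx = ox - V(ia,0), ty = oy - V(ia,1), tz = oz - V(ia,2);
    double u = (tx*px + ty*py + tz*pz) / det;
    if (u < 0 || u > 1) continue;
    double qx = ty*e1z - tz*e1y, qy = tz*e1x - tx*e1z, qz = tx*e1y - ty*e1x;
    double v = (dx*qx + dy*qy + dz*qz) / det;
    if (v < 0 || u + v > 1) continue;
    ts.push_back((e2x*qx + e2y*qy + e2z*qz) / det);
  }
  std::sort(ts.begin(), ts.end());
  return wrap(ts);
}

// ---------------------------------------------------------------------------
// exact closest point on mesh
// ---------------------------------------------------------------------------

static inline void closest_on_triangle(const double* p, const double* a,
                                       const double* b, const double* c,
                                       double* out) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double ac[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double ap[3] = { p[0]-a[0], p[1]-a[1], p[2]-a[2] };
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3] = { p[0]-b[0], p[1]-b[1], p[2]-b[2] };
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3] = { p[0]-c[0], p[1]-c[1], p[2]-c[2] };
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

struct Grid3 {
  double o[3], h[3];
  int n[3];
  std::vector< std::vector<int> > cells;

  void build(const NumericMatrix& V, const IntegerMatrix& F) {
    double lo[3] = { INF, INF, INF }, hi[3] = { -INF, -INF, -INF };
    for (int i = 0; i < V.nrow(); ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], V(i,k)); hi[k] = std::max(hi[k], V(i,k));
      }
    double ext[3], vol = 1;
    for (int k = 0; k < 3; ++k) {
      ext[k] = std::max(hi[k] - lo[k], 1e-6);
      vol *= ext[k];
    }
    double target = std::min(2.0e6, 4.0 * std::max(1, F.nrow()));
    double cell = std::cbrt(vol / target);
    for (int k = 0; k < 3; ++k) {
      n[k] = std::max(1, std::min(256, (int)std::ceil(ext[k] / cell)));
      o[k] = lo[k];
      h[k] = ext[k] / n[k];
    }
    cells.assign((size_t)n[0] * n[1] * n[2], std::vector<int>());
    for (int f = 0; f < F.nrow(); ++f) {
      int c0[3], c1[3];
      for (int k = 0; k < 3; ++k) {
        double tmin = INF, tmax = -INF;
        for (int j = 0; j < 3; ++j) {
          tmin = std::min(tmin, V(F(f,j),k));
          tmax = std::max(tmax, V(F(f,j),k));
        }
        c0[k] = std::min(n[k]-1, std::max(0, (int)std::floor((tmin - o[k]) / h[k])));
        c1[k] = std::min(n[k]-1, (int)std::floor((tmax - o[k]) / h[k]));
      }
      for (int z = c0[2]; z <= c1[2]; ++z)
        for (int y = c0[1]; y <= c1[1]; ++y)
          for (int x = c0[0]; x <= c1[0]; ++x)
            cells[((size_t)z * n[1] + y) * n[0] + x].push_back(f);
    }
  }
};

// closest surface point for each query; returns distances, points, faces
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  Grid3 g; g.build(V, F);
  int nq = P.nrow();
  NumericVector dist(nq);
  NumericMatrix cp(nq, 3);
  IntegerVector face(nq);
  // flat copies: Rcpp matrix proxies are too slow for the inner loop
  int nvv = V.nrow(), nff = F.nrow();
  std::vector<double> tv((size_t)nff * 9);
  for (int f = 0; f < nff; ++f)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        tv[(size_t)f * 9 + j * 3 + k] = V(F(f,j), k);
  (void)nvv;
  int maxring = g.n[0] + g.n[1] + g.n[2] + 2;
  double q[3], best_pt[3], pt[3];
  for (int i = 0; i < nq; ++i) {
    if ((i & 4095) == 0) Rcpp::checkUserInterrupt();
    for (int k = 0; k < 3; ++k) q[k] = P(i,k);
    int ci[3];
    for (int k = 0; k < 3; ++k) {
      ci[k] = (int)std::floor((q[k] - g.o[k]) / g.h[k]);
      ci[k] = std::max(0, std::min(g.n[k]-1, ci[k]));
    }
    double best2 = INF; int bestf = -1;
    best_pt[0] = best_pt[1] = best_pt[2] = NA_REAL;

    auto scan_cell = [&](int x, int y, int z) {
      if (x < 0 || x >= g.n[0] || y < 0 || y >= g.n[1] ||
          z < 0 || z >= g.n[2]) return;
      const std::vector<int>& fs =
        g.cells[((size_t)z * g.n[1] + y) * g.n[0] + x];
      for (int f : fs) {
        const double* base = &tv[(size_t)f * 9];
        closest_on_triangle(q, base, base + 3, base + 6, pt);
        double d2 = 0;
        for (int k = 0; k < 3; ++k) { double dd = pt[k] - q[k]; d2 += dd * dd; }
        if (d2 < best2) {
          best2 = d2; bestf = f;
          for (int k = 0; k < 3; ++k) best_pt[k] = pt[k];
        }
      }
    };

    for (int ring = 0; ring <= maxring; ++ring) {
      int x0 = ci[0]-ring, x1 = ci[0]+ring;
      int y0 = ci[1]-ring, y1 = ci[1]+ring;
      int z0 = ci[2]-ring, z1 = ci[2]+ring;
      if (ring == 0) scan_cell(ci[0], ci[1], ci[2]);
      else {
        // shell of the box only: two z faces, two y rows, two x columns
        for (int y = y0; y <= y1; ++y) for (int x = x0; x <= x1; ++x) {
          scan_cell(x, y, z0); scan_cell(x, y, z1);
        }
        for (int z = z0+1; z <= z1-1; ++z) {
          for (int x = x0; x <= x1; ++x) { scan_cell(x, y0, z); scan_cell(x, y1, z); }
          for (int y = y0+1; y <= y1-1; ++y) { scan_cell(x0, y, z); scan_cell(x1, y, z); }
        }
      }
      // exact lower bound on the distance to any cell outside the current box;
      // axes where the box already spans the whole grid impose no bound
      double bound = INF;
      bool covered = true;
      if (x0 > 0)          { bound = std::min(bound, q[0] - (g.o[0] + x0 * g.h[0])); covered = false; }
      if (x1 < g.n[0]-1)   { bound = std::min(bound, (g.o[0] + (x1+1) * g.h[0]) - q[0]); covered = false; }
      if (y0 > 0)          { bound = std::min(bound, q[1] - (g.o[1] + y0 * g.h[1])); covered = false; }
      if (y1 < g.n[1]-1)   { bound = std::min(bound, (g.o[1] + (y1+1) * g.h[1]) - q[1]); covered = false; }
      if (z0 > 0)          { bound = std::min(bound, q[2] - (g.o[2] + z0 * g.h[2])); covered = false; }
      if (z1 < g.n[2]-1)   { bound = std::min(bound, (g.o[2] + (z1+1) * g.h[2]) - q[2]); covered = false; }
      if (covered) break;
      if (best2 < INF && best2 <= bound * bound) break;
    }
    dist[i] = (best2 < INF) ? std::sqrt(best2) : INF;
    face[i] = bestf + 1;
    for (int k = 0; k < 3; ++k) cp(i,k) = best_pt[k];
  }
  return List::create(_["distance"] = dist, _["point"] = cp, _["face"] = face);
}

// ---------------------------------------------------------------------------
// marching tetrahedra
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, NumericVector spacing,
                        double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  // nudge values equal to iso
  double scale = 0;
  for (R_xlen_t i = 0; i < field.size(); ++i)
    scale = std::max(scale, std::fabs(field[i]));
  double eps = (scale > 0 ? scale : 1.0) * 1e-12;

  std::unordered_map<uint64_t,int> edge_vert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;

  // cube corner offsets (x,y,z)
  static const int CO[8][3] = { {0,0,0},{1,0,0},{1,1,0},{0,1,0},
                                {0,0,1},{1,0,1},{1,1,1},{0,1,1} };
  // six tetrahedra sharing the 0-6 diagonal, conforming across cubes
  static const int TETS[6][4] = { {0,1,2,6},{0,2,3,6},{0,3,7,6},
                                  {0,7,4,6},{0,4,5,6},{0,5,1,6} };

  double gx[8], gy[8], gz[8], val[8];
  R_xlen_t gid[8];

  auto edge_vertex = [&](R_xlen_t ga, R_xlen_t gb, double va, double vb,
                         double ax, double ay, double az,
                         double bx, double by, double bz) -> int {
    uint64_t key = ga < gb
      ? ((uint64_t)ga << 32 | (uint64_t)gb)
      : ((uint64_t)gb << 32 | (uint64_t)ga);
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    VX.push_back(ax + t * (bx - ax));
    VY.push_back(ay + t * (by - ay));
    VZ.push_back(az + t * (bz - az));
    int id = (int)VX.size() - 1;
    edge_vert[key] = id;
    return id;
  };

  auto emit = [&](int v0, int v1, int v2,
                  double inx, double iny, double inz,
                  double outx, double outy, double outz) {
    // orient so the normal points from inside (>= iso) to outside
    double ux = VX[v1]-VX[v0], uy = VY[v1]-VY[v0], uz = VZ[v1]-VZ[v0];
    double wx = VX[v2]-VX[v0], wy = VY[v2]-VY[v0], wz = VZ[v2]-VZ[v0];
    double nxn = uy*wz - uz*wy, nyn = uz*wx - ux*wz, nzn = ux*wy - uy*wx;
    double dx = outx - inx, dy = outy - iny, dz = outz - inz;
    if (nxn*dx + nyn*dy + nzn*dz >= 0) { FA.push_back(v0); FB.push_back(v1); FC.push_back(v2); }
    else                               { FA.push_back(v0); FB.push_back(v2); FC.push_back(v1); }
  };

  for (int z = 0; z + 1 < nz; ++z) {
    Rcpp::checkUserInterrupt();
    for (int y = 0; y + 1 < ny; ++y) {
      for (int x = 0; x + 1 < nx; ++x) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CO[c][0], cy = y + CO[c][1], cz = z + CO[c][2];
          gid[c] = (R_xlen_t)cz * sxy + (R_xlen_t)cy * nx + cx;
          double v = field[gid[c]];
          if (std::fabs(v - iso) < eps) v = iso - eps;  // ties break outside
          val[c] = v;
          gx[c] = origin[0] + cx * spacing[0];
          gy[c] = origin[1] + cy * spacing[1];
          gz[c] = origin[2] + cz * spacing[2];
          if (v > iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = { TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3] };
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (val[id[k]] > iso) ins[nin++] = id[k]; else outs[nout++] = id[k];
          }
          if (nin == 0 || nout == 0) continue;
          double icx=0, icy=0, icz=0, ocx=0, ocy=0, ocz=0;
          for (int k = 0; k < nin; ++k)  { icx+=gx[ins[k]]; icy+=gy[ins[k]]; icz+=gz[ins[k]]; }
          for (int k = 0; k < nout; ++k) { ocx+=gx[outs[k]]; ocy+=gy[outs[k]]; ocz+=gz[outs[k]]; }
          icx/=nin; icy/=nin; icz/=nin; ocx/=nout; ocy/=nout; ocz/=nout;
          auto ev = [&](int a, int b) {
            return edge_vertex(gid[a], gid[b], val[a], val[b],
                               gx[a], gy[a], gz[a], gx[b], gy[b], gz[b]);
          };
          if (nin == 1) {
            int v0 = ev(ins[0], outs[0]), v1 = ev(ins[0], outs[1]),
                v2 = ev(ins[0], outs[2]);
            emit(v0, v1, v2, icx, icy, icz, ocx, ocy, ocz);
          } else if (nin == 3) {
            int v0 = ev(ins[0], outs[0]), v1 = ev(ins[1], outs[0]),
                v2 = ev(ins[2], outs[0]);
            emit(v0, v1, v2, icx, icy, icz, ocx, ocy, ocz);
          } else { // 2 in, 2 out -> quad
            int v00 = ev(ins[0], outs[0]), v01 = ev(ins[0], outs[1]);
            int v10 = ev(ins[1], outs[0]), v11 = ev(ins[1], outs[1]);
            emit(v00, v01, v11, icx, icy, icz, ocx, ocy, ocz);
            emit(v00, v11, v10, icx, icy, icz, ocx, ocy, ocz);
          }
        }
      }
    }
  }
  int nv = (int)VX.size(), nf = (int)FA.size();
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) { Vm(i,0)=VX[i]; Vm(i,1)=VY[i]; Vm(i,2)=VZ[i]; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) { Fm(i,0)=FA[i]+1; Fm(i,1)=FB[i]+1; Fm(i,2)=FC[i]+1; }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, double h, std::vector<double>& d) {
  int n = (int)f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      double qq = q * h, vv = v[k] * h;
      s = ((f[q] + qq*qq) - (f[v[k]] + vv*vv)) / (2*qq - 2*vv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k+1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * h;
    while (zb[k+1] < qq) ++k;
    double vv = v[k] * h;
    d[q] = (f[v[k]] == INF) ? INF : (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// squared distance (mm^2) from every voxel to the nearest TRUE voxel
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t sxy = (R_xlen_t)nx * ny, N = sxy * nz;
  std::vector<double> D(N);
  for (R_xlen_t i = 0; i < N; ++i) D[i] = mask[i] ? 0.0 : INF;
  std::vector<double> f, d;
  // x pass
  f.resize(nx);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    R_xlen_t base = (R_xlen_t)z * sxy + (R_xlen_t)y * nx;
    bool any = false;
    for (int x = 0; x < nx; ++x) { f[x] = D[base + x]; if (f[x] < INF) any = true; }
    if (!any) continue;
    dt1d(f, spacing[0], d);
    for (int x = 0; x < nx; ++x) D[base + x] = d[x];
  }
  // y pass
  f.resize(ny);
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    R_xlen_t base = (R_xlen_t)z * sxy + x;
    bool any = false;
    for (int y = 0; y < ny; ++y) { f[y] = D[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
    if (!any) continue;
    dt1d(f, spacing[1], d);
    for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y];
  }
  // z pass
  f.resize(nz);
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    R_xlen_t base = (R_xlen_t)y * nx + x;
    bool any = false;
    for (int z = 0; z < nz; ++z) { f[z] = D[base + (R_xlen_t)z * sxy]; if (f[z] < INF) any = true; }
    if (!any) continue;
    dt1d(f, spacing[2], d);
    for (int z = 0; z < nz; ++z) D[base + (R_xlen_t)z * sxy] = d[z];
  }
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = D[i];
  return out;
}

// ---------------------------------------------------------------------------
// connected components (26) and hole filling (6-connected background)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t sxy = (R_xlen_t)nx * ny, N = sxy * nz;
  IntegerVector lab(N, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny), z = (int)(cur / sxy);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int X = x+dx, Y = y+dy, Z = z+dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          R_xlen_t t = (R_xlen_t)Z * sxy + (R_xlen_t)Y * nx + X;
          if (mask[t] && !lab[t]) { lab[t] = next; stack.push_back(t); }
        }
    }
  }
  return lab;
}

// fill cavities: background not 6-connected to the grid boundary -> foreground
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t sxy = (R_xlen_t)nx * ny, N = sxy * nz;
  std::vector<char> outside(N, 0);
  std::vector<R_xlen_t> stack;
  auto push = [&](int x, int y, int z) {
    R_xlen_t t = (R_xlen_t)z * sxy + (R_xlen_t)y * nx + x;
    if (!mask[t] && !outside[t]) { outside[t] = 1; stack.push_back(t); }
  };
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    push(x, y, 0); push(x, y, nz-1);
  }
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    push(x, 0, z); push(x, ny-1, z);
  }
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    push(0, y, z); push(nx-1, y, z);
  }
  const int NB[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int x = (int)(cur % nx), y = (int)((cur / nx) % ny), z = (int)(cur / sxy);
    for (int k = 0; k < 6; ++k) {
      int X = x+NB[k][0], Y = y+NB[k][1], Z = z+NB[k][2];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      push(X, Y, Z);
    }
  }
  LogicalVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// ---------------------------------------------------------------------------
// separable convolution along one axis (replicate padding, kernel normalized
// by the caller)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dims,
                                NumericVector kernel, int axis) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t sxy = (R_xlen_t)nx * ny, N = sxy * nz;
  int kl = kernel.size(), kc = kl / 2;
  NumericVector out(N);
  int n_ax = (axis == 0) ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1 ? nx : sxy);
  int n1 = (axis == 0) ? ny : nx;
  int n2 = (axis == 2) ? ny : nz;
  R_xlen_t s1 = (axis == 0) ? nx : 1;
  R_xlen_t s2 = (axis == 2) ? nx : sxy;
  std::vector<double> line(n_ax);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      R_xlen_t base = (R_xlen_t)j2 * s2 + (R_xlen_t)j1 * s1;
      for (int i = 0; i < n_ax; ++i) line[i] = vol[base + (R_xlen_t)i * stride];
      for (int i = 0; i < n_ax; ++i) {
        double acc = 0;
        for (int k = 0; k < kl; ++k) {
          int idx = i + k - kc;
          if (idx < 0) idx = 0;
          if (idx >= n_ax) idx = n_ax - 1;
          acc += kernel[k] * line[idx];
        }
        out[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  return out;
}
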