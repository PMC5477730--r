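#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

// Exact point-to-triangle-mesh distances. Each query point is resolved to
// the nearest point on the full triangulated surface (faces, edges and
// vertices), accelerated by a uniform grid over triangle bounding boxes so
// that directed Hausdorff distances over dense surface samplings stay fast.

struct V3 { double x, y, z; };

static inline V3 sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double dist2(const V3& a, const V3& b) {
  double dx=a.x-b.x, dy=a.y-b.y, dz=a.z-b.z; return dx*dx+dy*dy+dz*dz;
}
static inline V3 lerp(const V3& a, const V3& b, double t) {
  return {a.x + t*(b.x-a.x), a.y + t*(b.y-a.y), a.z + t*(b.z-a.z)};
}

static double seg_dist2(const V3& p, const V3& a, const V3& b) {
  V3 ab = sub(b, a), ap = sub(p, a);
  double denom = dot(ab, ab);
  if (denom <= 0.0) return dist2(p, a);
  double t = dot(ap, ab) / denom;
  t = std::max(0.0, std::min(1.0, t));
  return dist2(p, lerp(a, b, t));
}

// Closest-point-on-triangle (Ericson, Real-Time Collision Detection, 5.1.5)
static double tri_dist2(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return dist2(p, a);
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return dist2(p, b);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return dist2(p, lerp(a, b, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return dist2(p, c);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return dist2(p, lerp(a, c, w));
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2(p, lerp(b, c, w));
  }
  double denom = va + vb + vc;
  if (denom <= 0.0) {  // degenerate (zero-area) triangle: nearest edge
    return std::min({seg_dist2(p, a, b), seg_dist2(p, b, c), seg_dist2(p, a, c)});
  }
  double v = vb / denom, w = vc / denom;
  V3 q = {a.x + ab.x*v + ac.x*w, a.y + ab.y*v + ac.y*w, a.z + ab.z*v + ac.z*w};
  return dist2(p, q);
}

// [[Rcpp::export(name = ".mesh_point_distances")]]
Rcpp::NumericVector mesh_point_distances(Rcpp::NumericMatrix verts,
                                         Rcpp::IntegerMatrix faces,
                                         Rcpp::NumericMatrix pts) {
  const int nv = verts.nrow(), nf = faces.nrow(), np = pts.nrow();
  std::vector<V3> V(nv);
  for (int i = 0; i < nv; i++) V[i] = {verts(i,0), verts(i,1), verts(i,2)};
  std::vector<int> FA(nf), FB(nf), FC(nf);
  for (int i = 0; i < nf; i++) {
    FA[i] = faces(i,0) - 1; FB[i] = faces(i,1) - 1; FC[i] = faces(i,2) - 1;
  }

  // mesh bounding box
  double lo[3] = {V[0].x, V[0].y, V[0].z}, hi[3] = {V[0].x, V[0].y, V[0].z};
  for (int i = 1; i < nv; i++) {
    lo[0] = std::min(lo[0], V[i].x); hi[0] = std::max(hi[0], V[i].x);
    lo[1] = std::min(lo[1], V[i].y); hi[1] = std::max(hi[1], V[i].y);
    lo[2] = std::min(lo[2], V[i].z); hi[2] = std::max(hi[2], V[i].z);
  }
  double ext[3];
  for (int d = 0; d < 3; d++) ext[d] = std::max(hi[d] - lo[d], 1e-9);
  // aim for ~2 triangles per occupied cell
  double target = std::cbrt((ext[0]*ext[1]*ext[2]) / std::max(1.0, nf / 2.0));
  int ncell[3];
  double h[3];
  for (int d = 0; d < 3; d++) {
    ncell[d] = std::max(1, std::min(128, (int)std::ceil(ext[d] / target)));
    h[d] = ext[d] / ncell[d];
  }
  auto cellOf = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / h[d]);
    return std::max(0, std::min(ncell[d] - 1, c));
  };
  const R_xlen_t ntot = (R_xlen_t)ncell[0] * ncell[1] * ncell[2];
  std::vector<std::vector<int>> cells(ntot);
  auto cellIdx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)ncell[0] * (j + (R_xlen_t)ncell[1] * k);
  };
  for (int f = 0; f < nf; f++) {
    const V3 &a = V[FA[f]], &b = V[FB[f]], &c = V[FC[f]];
    int i0 = cellOf(std::min({a.x, b.x, c.x}), 0), i1 = cellOf(std::max({a.x, b.x, c.x}), 0);
    int j0 = cellOf(std::min({a.y, b.y, c.y}), 1), j1 = cellOf(std::max({a.y, b.y, c.y}), 1);
    int k0 = cellOf(std::min({a.z, b.z, c.z}), 2), k1 = cellOf(std::max({a.z, b.z, c.z}), 2);
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++)
          cells[cellIdx(i, j, k)].push_back(f);
  }

  std::vector<int> stamp(nf, -1);
  Rcpp::NumericVector out(np);
  const int maxRing = std::max({ncell[0], ncell[1], ncell[2]});
  const double minh = std::min({h[0], h[1], h[2]});

  for (int q = 0; q < np; q++) {
    V3 p = {pts(q,0), pts(q,1), pts(q,2)};
    int ci = cellOf(p.x, 0), cj = cellOf(p.y, 1), ck = cellOf(p.z, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int m = 0; m <= maxRing; m++) {
      // every cell in ring m lies at least (m-1)*minh from p (p may sit
      // outside the grid, in which case this still under-estimates)
      double lb = (m - 1) * minh;
      if (m >= 1 && best < std::numeric_limits<double>::infinity() &&
          lb * lb >= best) break;
      int i0 = std::max(0, ci - m), i1 = std::min(ncell[0] - 1, ci + m);
      int j0 = std::max(0, cj - m), j1 = std::min(ncell[1] - 1, cj + m);
      int k0 = std::max(0, ck - m), k1 = std::min(ncell[2] - 1, ck + m);
      for (int k = k0; k <= k1; k++)
        for (int j = j0; j <= j1; j++)
          for (int i = i0; i <= i1; i++) {
            // only the shell of the ring (interior visited earlier)
            if (m > 0 && std::abs(i - ci) != m && std::abs(j - cj) != m &&
                std::abs(k - ck) != m) continue;
            // distance from p to this cell's box
            double bx0 = lo[0] + i * h[0], bx1 = bx0 + h[0];
            double by0 = lo[1] + j * h[1], by1 = by0 + h[1];
            double bz0 = lo[2] + k * h[2], bz1 = bz0 + h[2];
            double dx = std::max({bx0 - p.x, 0.0, p.x - bx1});
            double dy = std::max({by0 - p.y, 0.0, p.y - by1});
            double dz = std::max({bz0 - p.z, 0.0, p.z - bz1});
            double bd2 = dx*dx + dy*dy + dz*dz;
            if (bd2 >= best) continue;
            for (int f : cells[cellIdx(i, j, k)]) {
              if (stamp[f] == q) continue;
              stamp[f] = q;
              double d2 = tri_dist2(p, V[FA[f]], V[FB[f]], V[FC[f]]);
              if (d2 < best) best = d2;
            }
          }
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
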