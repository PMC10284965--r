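#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Triangle-triangle overlap test (Moller 1997 interval method) with a
// 2D test for the coplanar case. Exactly-touching configurations
// (shared edges/vertices by position) are not counted as intersections.

static inline void cross3(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline void isect_interval(double vv0, double vv1, double vv2,
                                  double d0, double d1, double d2,
                                  double *t0, double *t1) {
  // vv0 is the lone vertex: the crossing edges are (0,1) and (0,2)
  *t0 = vv0 + (vv1 - vv0) * d0 / (d0 - d1);
  *t1 = vv0 + (vv2 - vv0) * d0 / (d0 - d2);
}

// 2D helpers for the coplanar case
static inline double orient2d(const double *a, const double *b, const double *c) {
  return (b[0] - a[0]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[0] - a[0]);
}

static bool seg_seg_proper(const double *p1, const double *p2,
                           const double *q1, const double *q2, double eps) {
  double d1 = orient2d(q1, q2, p1), d2 = orient2d(q1, q2, p2);
  double d3 = orient2d(p1, p2, q1), d4 = orient2d(p1, p2, q2);
  return ((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
         ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps));
}

static bool point_in_tri_strict(const double *p, const double *a,
                                const double *b, const double *c, double eps) {
  double d1 = orient2d(a, b, p), d2 = orient2d(b, c, p), d3 = orient2d(c, a, p);
  return (d1 > eps && d2 > eps && d3 > eps) ||
         (d1 < -eps && d2 < -eps && d3 < -eps);
}

static bool coplanar_tri_tri(const double *n, const double *v0,
                             const double *v1, const double *v2,
                             const double *u0, const double *u1,
                             const double *u2, double eps) {
  // project onto the dominant axis plane
  int i0, i1;
  double a[3] = {std::fabs(n[0]), std::fabs(n[1]), std::fabs(n[2])};
  if (a[0] > a[1]) {
    if (a[0] > a[2]) { i0 = 1; i1 = 2; } else { i0 = 0; i1 = 1; }
  } else {
    if (a[2] > a[1]) { i0 = 0; i1 = 1; } else { i0 = 0; i1 = 2; }
  }
  double V0[2] = {v0[i0], v0[i1]}, V1[2] = {v1[i0], v1[i1]},
         V2[2] = {v2[i0], v2[i1]};
  double U0[2] = {u0[i0], u0[i1]}, U1[2] = {u1[i0], u1[i1]},
         U2[2] = {u2[i0], u2[i1]};
  const double *tv[3] = {V0, V1, V2};
  const double *tu[3] = {U0, U1, U2};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (seg_seg_proper(tv[i], tv[(i + 1) % 3], tu[j], tu[(j + 1) % 3], eps))
        return true;
  for (int i = 0; i < 3; ++i) {
    if (point_in_tri_strict(tv[i], U0, U1, U2, eps)) return true;
    if (point_in_tri_strict(tu[i], V0, V1, V2, eps)) return true;
  }
  return false;
}

static bool tri_tri_overlap(const double *v0, const double *v1, const double *v2,
                            const double *u0, const double *u1, const double *u2,
                            double eps) {
  double e1[3], e2[3], n1[3];
  for (int k = 0; k < 3; ++k) { e1[k] = v1[k] - v0[k]; e2[k] = v2[k] - v0[k]; }
  cross3(e1, e2, n1);
  double d1 = -dot3(n1, v0);
  double du0 = dot3(n1, u0) + d1, du1 = dot3(n1, u1) + d1, du2 = dot3(n1, u2) + d1;
  if (std::fabs(du0) < eps) du0 = 0;
  if (std::fabs(du1) < eps) du1 = 0;
  if (std::fabs(du2) < eps) du2 = 0;
  double du01 = du0 * du1, du02 = du0 * du2;
  if (du01 > 0 && du02 > 0) return false;  // all on one side

  double f1[3], f2[3], n2[3];
  for (int k = 0; k < 3; ++k) { f1[k] = u1[k] - u0[k]; f2[k] = u2[k] - u0[k]; }
  cross3(f1, f2, n2);
  double d2 = -dot3(n2, u0);
  double dv0 = dot3(n2, v0) + d2, dv1 = dot3(n2, v1) + d2, dv2 = dot3(n2, v2) + d2;
  if (std::fabs(dv0) < eps) dv0 = 0;
  if (std::fabs(dv1) < eps) dv1 = 0;
  if (std::fabs(dv2) < eps) dv2 = 0;
  double dv01 = dv0 * dv1, dv02 = dv0 * dv2;
  if (dv01 > 0 && dv02 > 0) return false;

  if (du0 == 0 && du1 == 0 && du2 == 0)
    return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2, eps);

  // direction of the intersection line
  double dvec[3];
  cross3(n1, n2, dvec);
  double amax = std::fabs(dvec[0]);
  int index = 0;
  if (std::fabs(dvec[1]) > amax) { amax = std::fabs(dvec[1]); index = 1; }
  if (std::fabs(dvec[2]) > amax) index = 2;
  double vp0 = v0[index], vp1 = v1[index], vp2 = v2[index];
  double up0 = u0[index], up1 = u1[index], up2 = u2[index];

  double isect1[2], isect2[2];
  // arrange so the lone vertex is in the middle
  auto arrange = [&](double vv0, double vv1, double vv2, double dd0,
                     double dd1, double dd2, double *t0, double *t1) -> bool {
    double d01 = dd0 * dd1, d02 = dd0 * dd2;
    if (d01 > 0) isect_interval(vv2, vv0, vv1, dd2, dd0, dd1, t0, t1);
    else if (d02 > 0) isect_interval(vv1, vv0, vv2, dd1, dd0, dd2, t0, t1);
    else if (dd1 * dd2 > 0 || dd0 != 0)
      isect_interval(vv0, vv1, vv2, dd0, dd1, dd2, t0, t1);
    else if (dd1 != 0) isect_interval(vv1, vv0, vv2, dd1, dd0, dd2, t0, t1);
    else if (dd2 != 0) isect_interval(vv2, vv0, vv1, dd2, dd0, dd1, t0, t1);
    else return false;  // degenerate: coplanar handled elsewhere
    return true;
  };
  if (!arrange(vp0, vp1, vp2, dv0, dv1, dv2, &isect1[0], &isect1[1]))
    return false;
  if (!arrange(up0, up1, up2, du0, du1, du2, &isect2[0], &isect2[1]))
    return false;
  if (isect1[0] > isect1[1]) std::swap(isect1[0], isect1[1]);
  if (isect2[0] > isect2[1]) std::swap(isect2[0], isect2[1]);
  // strict overlap: touching along the line does not count
  return (isect1[1] > isect2[0] + eps) && (isect2[1] > isect1[0] + eps);
}

// Pairs of non-adjacent (no shared vertex index) triangles that
// properly intersect (one-based face indices).
// [[Rcpp::export]]
IntegerMatrix cpp_self_intersection_pairs(NumericMatrix V, IntegerMatrix F) {
  std::vector<int> pf, pg;
  const int nf = F.nrow();
  if (nf < 2) return IntegerMatrix(0, 2);
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  double glo[3], ghi[3];
  for (int k = 0; k < 3; ++k) {
    glo[k] = std::numeric_limits<double>::infinity();
    ghi[k] = -std::numeric_limits<double>::infinity();
  }
  double avg = 0;
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      double a = V(i0, k), b = V(i1, k), c = V(i2, k);
      double lo = std::min(a, std::min(b, c));
      double hi = std::max(a, std::max(b, c));
      blo[3 * f + k] = lo;
      bhi[3 * f + k] = hi;
      glo[k] = std::min(glo[k], lo);
      ghi[k] = std::max(ghi[k], hi);
      avg += hi - lo;
    }
  }
  avg /= 3.0 * nf;
  double cell = avg > 0 ? 2.0 * avg : 1.0;
  int ncell[3];
  for (int k = 0; k < 3; ++k) {
    ncell[k] = std::max(1, std::min(64, (int)std::ceil((ghi[k] - glo[k]) / cell)));
  }
  const int ntot = ncell[0] * ncell[1] * ncell[2];
  std::vector<std::vector<int> > bins(ntot);
  std::vector<int> c0(nf), c1(nf), c2(nf), C0(nf), C1(nf), C2(nf);
  for (int f = 0; f < nf; ++f) {
    int lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      double span = ghi[k] - glo[k];
      double w = span > 0 ? span : 1.0;
      int l = (int)((blo[3 * f + k] - glo[k]) / w * ncell[k]);
      int h = (int)((bhi[3 * f + k] - glo[k]) / w * ncell[k]);
      lo[k] = std::max(0, std::min(ncell[k] - 1, l));
      hi[k] = std::max(0, std::min(ncell[k] - 1, h));
    }
    c0[f] = lo[0]; c1[f] = lo[1]; c2[f] = lo[2];
    C0[f] = hi[0]; C1[f] = hi[1]; C2[f] = hi[2];
    for (int x = lo[0]; x <= hi[0]; ++x)
      for (int y = lo[1]; y <= hi[1]; ++y)
        for (int z = lo[2]; z <= hi[2]; ++z)
          bins[(x * ncell[1] + y) * ncell[2] + z].push_back(f);
  }
  double scale = 0;
  for (int k = 0; k < 3; ++k) scale = std::max(scale, ghi[k] - glo[k]);
  const double eps = 1e-10 * (scale > 0 ? scale : 1.0);

  std::unordered_set<uint64_t> seen;
  for (int b = 0; b < ntot; ++b) {
    const std::vector<int> &lst = bins[b];
    const size_t m = lst.size();
    for (size_t ii = 0; ii + 1 < m; ++ii) {
      for (size_t jj = ii + 1; jj < m; ++jj) {
        int f = std::min(lst[ii], lst[jj]);
        int g = std::max(lst[ii], lst[jj]);
        // bbox overlap
        bool ok = true;
        for (int k = 0; k < 3; ++k) {
          if (blo[3 * f + k] > bhi[3 * g + k] + eps ||
              blo[3 * g + k] > bhi[3 * f + k] + eps) {
            ok = false;
            break;
          }
        }
        if (!ok) continue;
        // skip pairs sharing a vertex index
        int fa = F(f, 0), fb = F(f, 1), fc = F(f, 2);
        int ga = F(g, 0), gb = F(g, 1), gc = F(g, 2);
        if (fa == ga || fa == gb || fa == gc || fb == ga || fb == gb ||
            fb == gc || fc == ga || fc == gb || fc == gc)
          continue;
        uint64_t key = (uint64_t)f * (uint64_t)nf + (uint64_t)g;
        if (!seen.insert(key).second) continue;
        int i0 = fa - 1, i1 = fb - 1, i2 = fc - 1;
        int j0 = ga - 1, j1 = gb - 1, j2 = gc - 1;
        double v0[3] = {V(i0, 0), V(i0, 1), V(i0, 2)};
        double v1[3] = {V(i1, 0), V(i1, 1), V(i1, 2)};
        double v2[3] = {V(i2, 0), V(i2, 1), V(i2, 2)};
        double u0[3] = {V(j0, 0), V(j0, 1), V(j0, 2)};
        double u1[3] = {V(j1, 0), V(j1, 1), V(j1, 2)};
        double u2[3] = {V(j2, 0), V(j2, 1), V(j2, 2)};
        if (tri_tri_overlap(v0, v1, v2, u0, u1, u2, eps)) {
          pf.push_back(f + 1);
          pg.push_back(g + 1);
        }
      }
    }
  }
  IntegerMatrix out(pf.size(), 2);
  for (size_t r = 0; r < pf.size(); ++r) {
    out(r, 0) = pf[r];
    out(r, 1) = pg[r];
  }
  return out;
}

// Count of properly intersecting non-adjacent triangle pairs.
// [[Rcpp::export]]
int cpp_self_intersections(NumericMatrix V, IntegerMatrix F) {
  return cpp_self_intersection_pairs(V, F).nrow();
}
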