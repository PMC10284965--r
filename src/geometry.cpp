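#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection, 5.1.5).
static inline void closest_pt_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = 0, d2 = 0;
  for (int k = 0; k < 3; ++k) { d1 += ab[k] * ap[k]; d2 += ac[k] * ap[k]; }
  if (d1 <= 0 && d2 <= 0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1; bary[1] = 0; bary[2] = 0;
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = 0, d4 = 0;
  for (int k = 0; k < 3; ++k) { d3 += ab[k] * bp[k]; d4 += ac[k] * bp[k]; }
  if (d3 >= 0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0; bary[1] = 1; bary[2] = 0;
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = 0, d6 = 0;
  for (int k = 0; k < 3; ++k) { d5 += ab[k] * cp[k]; d6 += ac[k] * cp[k]; }
  if (d6 >= 0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0; bary[1] = 0; bary[2] = 1;
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// Exact closest points on a triangle mesh for a set of query points.
// V: n x 3 vertices, F: m x 3 one-based faces, Q: q x 3 queries.
// Returns closest points, squared distances, triangle index (one-based)
// and barycentric coordinates. Brute force over triangles with a
// nearest-vertex seed and per-triangle bounding-box rejection.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nv = V.nrow(), nf = F.nrow();
  NumericMatrix P(nq, 3), B(nq, 3);
  NumericVector D(nq);
  IntegerVector T(nq);

  // triangle bounding boxes
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      double a = V(i0, k), b = V(i1, k), c = V(i2, k);
      double lo = a < b ? a : b; lo = lo < c ? lo : c;
      double hi = a > b ? a : b; hi = hi > c ? hi : c;
      blo[3 * f + k] = lo;
      bhi[3 * f + k] = hi;
    }
  }

  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    // seed with nearest vertex
    double best = std::numeric_limits<double>::infinity();
    for (int i = 0; i < nv; ++i) {
      double d = 0;
      for (int k = 0; k < 3; ++k) {
        double t = V(i, k) - p[k];
        d += t * t;
      }
      if (d < best) best = d;
    }
    best += 1e-12;
    int btri = -1;
    double bp[3] = {0, 0, 0}, bb[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      // bbox rejection
      double dbox = 0;
      for (int k = 0; k < 3; ++k) {
        double d = 0;
        if (p[k] < blo[3 * f + k]) d = blo[3 * f + k] - p[k];
        else if (p[k] > bhi[3 * f + k]) d = p[k] - bhi[3 * f + k];
        dbox += d * d;
      }
      if (dbox > best) continue;
      int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
      double a[3] = {V(i0, 0), V(i0, 1), V(i0, 2)};
      double b[3] = {V(i1, 0), V(i1, 1), V(i1, 2)};
      double c[3] = {V(i2, 0), V(i2, 1), V(i2, 2)};
      double out[3], bar[3];
      closest_pt_tri(p, a, b, c, out, bar);
      double d = 0;
      for (int k = 0; k < 3; ++k) {
        double t = out[k] - p[k];
        d += t * t;
      }
      if (d < best || btri < 0) {
        best = d;
        btri = f;
        for (int k = 0; k < 3; ++k) { bp[k] = out[k]; bb[k] = bar[k]; }
      }
    }
    for (int k = 0; k < 3; ++k) { P(q, k) = bp[k]; B(q, k) = bb[k]; }
    D[q] = best;
    T[q] = btri + 1;
  }
  return List::create(_["points"] = P, _["dist2"] = D, _["tri"] = T,
                      _["bary"] = B);
}

// For each row of A, the minimum Euclidean distance to any row of B.
// [[Rcpp::export]]
NumericVector cpp_min_cross_dist(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// First-hit distances for rays (one per row) against a mesh
// (Moeller-Trumbore). Returns t >= 0 of the nearest hit, NA if none.
// [[Rcpp::export]]
NumericVector cpp_ray_mesh(NumericMatrix O, NumericMatrix Dir,
                           NumericMatrix V, IntegerMatrix F) {
  const int nq = O.nrow(), nf = F.nrow();
  NumericVector out(nq, NA_REAL);
  const double eps = 1e-12;
  for (int q = 0; q < nq; ++q) {
    double o[3] = {O(q, 0), O(q, 1), O(q, 2)};
    double d[3] = {Dir(q, 0), Dir(q, 1), Dir(q, 2)};
    double best = std::numeric_limits<double>::infinity();
    bool hit = false;
    for (int f = 0; f < nf; ++f) {
      int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
      double e1[3], e2[3], tv[3];
      for (int k = 0; k < 3; ++k) {
        e1[k] = V(i1, k) - V(i0, k);
        e2[k] = V(i2, k) - V(i0, k);
        tv[k] = o[k] - V(i0, k);
      }
      double pv[3] = {d[1] * e2[2] - d[2] * e2[1],
                      d[2] * e2[0] - d[0] * e2[2],
                      d[0] * e2[1] - d[1] * e2[0]};
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                      tv[2] * e1[0] - tv[0] * e1[2],
                      tv[0] * e1[1] - tv[1] * e1[0]};
      double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
      if (t > 1e-9 && t < best) {
        best = t;
        hit = true;
      }
    }
    if (hit) out[q] = best;
  }
  return out;
}
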