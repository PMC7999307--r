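#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to point p, with barycentric coordinates.
// Region-based construction after the standard computational-geometry
// treatment; exact at vertices/edges so barycentric zeros are exact.
static inline void closest_on_triangle(const double *p,
                                       const double *a, const double *b,
                                       const double *c,
                                       double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { // vertex a
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { // vertex b
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { // edge ab
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { // vertex c
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { // edge ac
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) { // edge bc
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  // interior
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

// Distance-limited nearest-surface-point query: for each row of P, the
// globally nearest point on the triangulated surface (V, F) if within d,
// scanning faces in index order with bounding-box pruning so exact ties
// resolve to the lowest face index. Equals exhaustive search by construction.
// [[Rcpp::export]]
List closest_points_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                        double d) {
  int np = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  if (d <= 0) stop("distance threshold d must be > 0");

  // per-face bounding boxes
  std::vector<double> lo(3 * nf), hi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      double a = V(F(f, 0) - 1, k), b = V(F(f, 1) - 1, k),
             c = V(F(f, 2) - 1, k);
      double mn = a < b ? a : b; if (c < mn) mn = c;
      double mx = a > b ? a : b; if (c > mx) mx = c;
      lo[3 * f + k] = mn;
      hi[3 * f + k] = mx;
    }
  }

  LogicalVector found(np);
  IntegerVector face(np);
  NumericVector dist(np);
  NumericMatrix point(np, 3), bary(np, 3);

  for (int i = 0; i < np; ++i) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double best2 = d * d;       // search capped at threshold
    int best_f = -1;
    double bp[3] = {0, 0, 0}, bb[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      // squared distance to face bbox
      double db2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double e = 0.0;
        if (p[k] < lo[3 * f + k]) e = lo[3 * f + k] - p[k];
        else if (p[k] > hi[3 * f + k]) e = p[k] - hi[3 * f + k];
        db2 += e * e;
      }
      if (db2 > best2) continue;
      double av[3], bv[3], cv[3];
      for (int k = 0; k < 3; ++k) {
        av[k] = V(F(f, 0) - 1, k);
        bv[k] = V(F(f, 1) - 1, k);
        cv[k] = V(F(f, 2) - 1, k);
      }
      double q[3], w[3];
      closest_on_triangle(p, av, bv, cv, q, w);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double e = p[k] - q[k];
        d2 += e * e;
      }
      // strict improvement: exact ties keep the earlier (lower) face index;
      // the first acceptance is inclusive so that distance == d is found
      if (d2 < best2 || (best_f < 0 && d2 <= best2)) {
        best2 = d2;
        best_f = f;
        for (int k = 0; k < 3; ++k) { bp[k] = q[k]; bb[k] = w[k]; }
      }
    }
    if (best_f >= 0) {
      found[i] = true;
      face[i] = best_f + 1;
      dist[i] = std::sqrt(best2);
      for (int k = 0; k < 3; ++k) {
        point(i, k) = bp[k];
        bary(i, k) = bb[k];
      }
    } else {
      found[i] = false;
      face[i] = NA_INTEGER;
      dist[i] = NA_REAL;
      for (int k = 0; k < 3; ++k) {
        point(i, k) = NA_REAL;
        bary(i, k) = NA_REAL;
      }
    }
  }
  return List::create(_["found"] = found, _["face"] = face,
                      _["dist"] = dist, _["point"] = point, _["bary"] = bary);
}
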