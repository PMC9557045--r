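#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to point p. Ericson, Real-Time
// Collision Detection, 5.1.5: region classification via barycentric signs.
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Per-query-point closest point on a triangle mesh. Faces with area below
// eps_area are skipped; caller must guarantee at least one valid face.
// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                            double eps_area = 1e-12) {
  int n = P.nrow(), m = F.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector face(n);

  // Precompute triangle vertices and bounding spheres for pruning.
  std::vector<double> TA(3 * m), TB(3 * m), TC(3 * m), CX(m), CY(m), CZ(m),
      R(m);
  std::vector<bool> ok(m);
  int nvalid = 0;
  for (int t = 0; t < m; ++t) {
    int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
    for (int k = 0; k < 3; ++k) {
      TA[3 * t + k] = V(ia, k);
      TB[3 * t + k] = V(ib, k);
      TC[3 * t + k] = V(ic, k);
    }
    double e1[3], e2[3], cr[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = TB[3 * t + k] - TA[3 * t + k];
      e2[k] = TC[3 * t + k] - TA[3 * t + k];
    }
    cr[0] = e1[1] * e2[2] - e1[2] * e2[1];
    cr[1] = e1[2] * e2[0] - e1[0] * e2[2];
    cr[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double area2 = std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
    ok[t] = (0.5 * area2 > eps_area);
    if (ok[t]) ++nvalid;
    double cx = (TA[3 * t] + TB[3 * t] + TC[3 * t]) / 3.0;
    double cy = (TA[3 * t + 1] + TB[3 * t + 1] + TC[3 * t + 1]) / 3.0;
    double cz = (TA[3 * t + 2] + TB[3 * t + 2] + TC[3 * t + 2]) / 3.0;
    CX[t] = cx; CY[t] = cy; CZ[t] = cz;
    double r = 0.0;
    for (int k = 0; k < 3; ++k) {
      const double *vv = (k == 0) ? &TA[3 * t] : (k == 1 ? &TB[3 * t] : &TC[3 * t]);
      double dx = vv[0] - cx, dy = vv[1] - cy, dz = vv[2] - cz;
      double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (rr > r) r = rr;
    }
    R[t] = r;
  }
  if (nvalid == 0) stop("all target faces are degenerate");

  std::vector<double> dcent(m);
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = DBL_MAX, bq[3] = {0, 0, 0};
    int bt = -1;
    // seed with the nearest-centroid triangle so the sphere bound prunes
    // nearly everything on well-shaped meshes
    int seed = -1;
    double dmin = DBL_MAX;
    for (int t = 0; t < m; ++t) {
      double dx = p[0] - CX[t], dy = p[1] - CY[t], dz = p[2] - CZ[t];
      dcent[t] = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (ok[t] && dcent[t] < dmin) { dmin = dcent[t]; seed = t; }
    }
    if (seed >= 0) {
      double q[3];
      closest_on_tri(p, &TA[3 * seed], &TB[3 * seed], &TC[3 * seed], q);
      best = (p[0] - q[0]) * (p[0] - q[0]) + (p[1] - q[1]) * (p[1] - q[1]) +
             (p[2] - q[2]) * (p[2] - q[2]);
      bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
      bt = seed;
    }
    for (int t = 0; t < m; ++t) {
      if (!ok[t] || t == seed) continue;
      double dc = dcent[t] - R[t];
      if (dc > 0.0 && dc * dc >= best) continue;  // sphere lower bound
      double q[3];
      closest_on_tri(p, &TA[3 * t], &TB[3 * t], &TC[3 * t], q);
      double d2 = (p[0] - q[0]) * (p[0] - q[0]) +
                  (p[1] - q[1]) * (p[1] - q[1]) +
                  (p[2] - q[2]) * (p[2] - q[2]);
      if (d2 < best) {
        best = d2;
        bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
        bt = t;
      }
    }
    dist[i] = std::sqrt(best);
    closest(i, 0) = bq[0]; closest(i, 1) = bq[1]; closest(i, 2) = bq[2];
    face[i] = bt + 1;  // 1-based
  }
  return List::create(_["dist"] = dist, _["closest"] = closest,
                      _["face"] = face);
}

// For each row of A, minimum Euclidean distance to any row of B (any
// common dimensionality).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimensionality mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = DBL_MAX;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Closest point on a closed/open 2D polyline given as consecutive segment
// endpoints S1[j,] -> S2[j,].
// [[Rcpp::export]]
List cpp_closest_point_polyline(NumericMatrix P, NumericMatrix S1,
                                NumericMatrix S2) {
  int n = P.nrow(), m = S1.nrow();
  NumericVector dist(n);
  NumericMatrix foot(n, 2);
  for (int i = 0; i < n; ++i) {
    double px = P(i, 0), py = P(i, 1);
    double best = DBL_MAX, fx = 0, fy = 0;
    for (int j = 0; j < m; ++j) {
      double ax = S1(j, 0), ay = S1(j, 1);
      double bx = S2(j, 0), by = S2(j, 1);
      double vx = bx - ax, vy = by - ay;
      double L2 = vx * vx + vy * vy;
      double t = 0.0;
      if (L2 > 0.0) {
        t = ((px - ax) * vx + (py - ay) * vy) / L2;
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
      }
      double qx = ax + t * vx, qy = ay + t * vy;
      double d2 = (px - qx) * (px - qx) + (py - qy) * (py - qy);
      if (d2 < best) { best = d2; fx = qx; fy = qy; }
    }
    dist[i] = std::sqrt(best);
    foot(i, 0) = fx; foot(i, 1) = fy;
  }
  return List::create(_["dist"] = dist, _["foot"] = foot);
}

// Orthographic binary silhouette: fill the 2D projections of all triangles
// into an nx x ny pixel grid. V2 holds projected (u, v) vertex coordinates
// in mm; pixel (i, j) center is at (umin + (i - 0.5) * sp, vmin + (j - 0.5) * sp).
// Returns an nx x ny integer matrix (1 = foreground).
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_silhouette(NumericMatrix V2, IntegerMatrix F,
                                       double umin, double vmin, double sp,
                                       int nx, int ny) {
  IntegerMatrix img(nx, ny);
  int m = F.nrow();
  for (int t = 0; t < m; ++t) {
    double ax = V2(F(t, 0), 0), ay = V2(F(t, 0), 1);
    double bx = V2(F(t, 1), 0), by = V2(F(t, 1), 1);
    double cx = V2(F(t, 2), 0), cy = V2(F(t, 2), 1);
    double xmin = std::min(ax, std::min(bx, cx));
    double xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy));
    double ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::floor((xmin - umin) / sp - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - umin) / sp + 0.5));
    int j0 = std::max(0, (int)std::floor((ymin - vmin) / sp - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - vmin) / sp + 0.5));
    double det = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    if (std::fabs(det) < 1e-14) continue;  // edge-on triangle
    for (int i = i0; i <= i1; ++i) {
      double px = umin + (i + 0.5) * sp;
      for (int j = j0; j <= j1; ++j) {
        if (img(i, j)) continue;
        double py = vmin + (j + 0.5) * sp;
        double w0 = ((bx - px) * (cy - py) - (cx - px) * (by - py)) / det;
        double w1 = ((cx - px) * (ay - py) - (ax - px) * (cy - py)) / det;
        double w2 = 1.0 - w0 - w1;
        if (w0 >= -1e-9 && w1 >= -1e-9 && w2 >= -1e-9) img(i, j) = 1;
      }
    }
  }
  return img;
}
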