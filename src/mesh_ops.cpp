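#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, 5.1.5.
static inline void closestPointTriangle(const double *p, const double *a,
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
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
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
    for (int i = 0; i < 3; ++i) out[i] = c[i];
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

// Closest point on the mesh for each query (brute force over faces).
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int nq = Q.nrow(), nf = F.nrow();
  NumericMatrix P(nq, 3);
  IntegerVector face(nq);
  NumericVector dist(nq);
  double a[3], b[3], c[3], p[3], cp[3];
  for (int q = 0; q < nq; ++q) {
    for (int i = 0; i < 3; ++i) p[i] = Q(q, i);
    double best = R_PosInf;
    int bestf = -1;
    double bestp[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      for (int i = 0; i < 3; ++i) {
        a[i] = V(ia, i);
        b[i] = V(ib, i);
        c[i] = V(ic, i);
      }
      closestPointTriangle(p, a, b, c, cp);
      double d2 = 0;
      for (int i = 0; i < 3; ++i) d2 += (cp[i] - p[i]) * (cp[i] - p[i]);
      if (d2 < best) {
        best = d2;
        bestf = f;
        for (int i = 0; i < 3; ++i) bestp[i] = cp[i];
      }
    }
    for (int i = 0; i < 3; ++i) P(q, i) = bestp[i];
    face[q] = bestf + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["point"] = P, _["face"] = face, _["distance"] = dist);
}

// All intersections of one line (origin, direction, both senses) with the
// mesh, by Moller-Trumbore. Returns t values (signed distance along the
// direction), face indices (1-based) and dot(face normal, direction).
// [[Rcpp::export]]
List cpp_ray_hits(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                  NumericVector dir) {
  int nf = F.nrow();
  std::vector<double> ts, dots;
  std::vector<int> fids;
  std::vector<double> px, py, pz;
  const double eps = 1e-12;
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double e1[3], e2[3], a[3];
    for (int i = 0; i < 3; ++i) {
      a[i] = V(ia, i);
      e1[i] = V(ib, i) - a[i];
      e2[i] = V(ic, i) - a[i];
    }
    double pvec[3] = {dir[1] * e2[2] - dir[2] * e2[1],
                      dir[2] * e2[0] - dir[0] * e2[2],
                      dir[0] * e2[1] - dir[1] * e2[0]};
    double det = e1[0] * pvec[0] + e1[1] * pvec[1] + e1[2] * pvec[2];
    if (std::fabs(det) < eps) continue;
    double inv = 1.0 / det;
    double tvec[3];
    for (int i = 0; i < 3; ++i) tvec[i] = origin[i] - a[i];
    double u = (tvec[0] * pvec[0] + tvec[1] * pvec[1] + tvec[2] * pvec[2]) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) continue;
    double qvec[3] = {tvec[1] * e1[2] - tvec[2] * e1[1],
                      tvec[2] * e1[0] - tvec[0] * e1[2],
                      tvec[0] * e1[1] - tvec[1] * e1[0]};
    double v = (dir[0] * qvec[0] + dir[1] * qvec[1] + dir[2] * qvec[2]) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) continue;
    double t = (e2[0] * qvec[0] + e2[1] * qvec[1] + e2[2] * qvec[2]) * inv;
    // face normal (unnormalized) dot direction
    double n[3] = {e1[1] * e2[2] - e1[2] * e2[1], e1[2] * e2[0] - e1[0] * e2[2],
                   e1[0] * e2[1] - e1[1] * e2[0]};
    double nl = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    double dd = nl > 0 ? (n[0] * dir[0] + n[1] * dir[1] + n[2] * dir[2]) / nl : 0.0;
    ts.push_back(t);
    fids.push_back(f + 1);
    dots.push_back(dd);
    px.push_back(origin[0] + t * dir[0]);
    py.push_back(origin[1] + t * dir[1]);
    pz.push_back(origin[2] + t * dir[2]);
  }
  int n = ts.size();
  NumericMatrix P(n, 3);
  NumericVector tv(n), dv(n);
  IntegerVector fv(n);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = px[i];
    P(i, 1) = py[i];
    P(i, 2) = pz[i];
    tv[i] = ts[i];
    fv[i] = fids[i];
    dv[i] = dots[i];
  }
  return List::create(_["point"] = P, _["t"] = tv, _["face"] = fv,
                      _["normal_dot"] = dv);
}
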