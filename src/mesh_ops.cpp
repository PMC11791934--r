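#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, after Ericson, Real-Time
// Collision Detection, ch. 5.1.5. Writes result into out[3].
static inline double closest_point_tri(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) out[k] = b[k];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
      } else {
        double cp[3];
        for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int k = 0; k < 3; ++k) out[k] = c[k];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k)
                out[k] = a[k] + ab[k]*v + ac[k]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// Exact point-to-surface distances: minimum over all triangles.
// points: n x 3, verts: m x 3, faces: t x 3 (0-based).
// [[Rcpp::export]]
List cpp_point_mesh_dist(NumericMatrix points, NumericMatrix verts,
                         IntegerMatrix faces) {
  int n = points.nrow(), nf = faces.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  for (int i = 0; i < n; ++i) {
    double p[3] = { points(i,0), points(i,1), points(i,2) };
    double best = DBL_MAX, bestpt[3] = {0,0,0}, out[3];
    for (int f = 0; f < nf; ++f) {
      double a[3] = { verts(faces(f,0),0), verts(faces(f,0),1), verts(faces(f,0),2) };
      double b[3] = { verts(faces(f,1),0), verts(faces(f,1),1), verts(faces(f,1),2) };
      double c[3] = { verts(faces(f,2),0), verts(faces(f,2),1), verts(faces(f,2),2) };
      double d = closest_point_tri(p, a, b, c, out);
      if (d < best) {
        best = d;
        bestpt[0] = out[0]; bestpt[1] = out[1]; bestpt[2] = out[2];
      }
    }
    dist[i] = best;
    closest(i,0) = bestpt[0]; closest(i,1) = bestpt[1]; closest(i,2) = bestpt[2];
  }
  return List::create(_["dist"] = dist, _["closest"] = closest);
}

// Moller-Trumbore ray/triangle intersection. Returns t along dir or -1.
static inline double ray_tri(const double *o, const double *d,
                             const double *a, const double *b,
                             const double *c) {
  const double eps = 1e-12;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int k = 0; k < 3; ++k) { e1[k] = b[k]-a[k]; e2[k] = c[k]-a[k]; }
  pv[0] = d[1]*e2[2]-d[2]*e2[1];
  pv[1] = d[2]*e2[0]-d[0]*e2[2];
  pv[2] = d[0]*e2[1]-d[1]*e2[0];
  double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) tv[k] = o[k]-a[k];
  double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  qv[0] = tv[1]*e1[2]-tv[2]*e1[1];
  qv[1] = tv[2]*e1[0]-tv[0]*e1[2];
  qv[2] = tv[0]*e1[1]-tv[1]*e1[0];
  double v = (d[0]*qv[0] + d[1]*qv[1] + d[2]*qv[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
  return t;
}

// For each ray origin->dir, the intersection with the mesh farthest from
// the origin (t > 0). hit[i] = 0 when the ray misses every face.
// [[Rcpp::export]]
List cpp_ray_mesh_farthest(NumericVector origin, NumericMatrix dirs,
                           NumericMatrix verts, IntegerMatrix faces) {
  int n = dirs.nrow(), nf = faces.nrow();
  NumericVector tmax(n);
  IntegerVector hit(n);
  double o[3] = { origin[0], origin[1], origin[2] };
  for (int i = 0; i < n; ++i) {
    double d[3] = { dirs(i,0), dirs(i,1), dirs(i,2) };
    double best = -1.0;
    for (int f = 0; f < nf; ++f) {
      double a[3] = { verts(faces(f,0),0), verts(faces(f,0),1), verts(faces(f,0),2) };
      double b[3] = { verts(faces(f,1),0), verts(faces(f,1),1), verts(faces(f,1),2) };
      double c[3] = { verts(faces(f,2),0), verts(faces(f,2),1), verts(faces(f,2),2) };
      double t = ray_tri(o, d, a, b, c);
      if (t > 1e-9 && t > best) best = t;
    }
    tmax[i] = best;
    hit[i] = best > 0.0 ? 1 : 0;
  }
  return List::create(_["t"] = tmax, _["hit"] = hit);
}
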