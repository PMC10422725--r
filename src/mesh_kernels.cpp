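#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on a single triangle (Ericson, Real-Time Collision Detection).
static inline void closest_on_tri(const double *p,
                                  const double *a, const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

// For each query point, the closest point on the triangle mesh (V, F),
// F is 1-based. Returns closest points, distances and 1-based face ids.
// [[Rcpp::export]]
List cpp_closest_point_on_mesh(NumericMatrix points, NumericMatrix V, IntegerMatrix F) {
  int np = points.nrow(), nf = F.nrow();
  NumericMatrix cp(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  // Per-face centroid and bounding radius for a cheap reject test.
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
    double gx = (V(i0,0)+V(i1,0)+V(i2,0))/3.0;
    double gy = (V(i0,1)+V(i1,1)+V(i2,1))/3.0;
    double gz = (V(i0,2)+V(i1,2)+V(i2,2))/3.0;
    cx[f]=gx; cy[f]=gy; cz[f]=gz;
    double r2 = 0.0;
    int idx[3] = {i0,i1,i2};
    for (int j = 0; j < 3; ++j) {
      double dx = V(idx[j],0)-gx, dy = V(idx[j],1)-gy, dz = V(idx[j],2)-gz;
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  double a[3], b[3], c[3], q[3], best[3], p[3];
  int prevf = -1;   // spatial coherence: seed with the previous point's face
  for (int i = 0; i < np; ++i) {
    p[0]=points(i,0); p[1]=points(i,1); p[2]=points(i,2);
    double bestd2 = R_PosInf; int bestf = -1;
    if (prevf >= 0) {
      int i0 = F(prevf,0)-1, i1 = F(prevf,1)-1, i2 = F(prevf,2)-1;
      for (int k = 0; k < 3; ++k) { a[k]=V(i0,k); b[k]=V(i1,k); c[k]=V(i2,k); }
      closest_on_tri(p, a, b, c, q);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) { double dd = q[k]-p[k]; d2 += dd*dd; }
      bestd2 = d2; bestf = prevf;
      best[0]=q[0]; best[1]=q[1]; best[2]=q[2];
    }
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double dcen = std::sqrt(dx*dx+dy*dy+dz*dz);
      double lower = dcen - rad[f];
      if (lower > 0 && lower*lower >= bestd2) continue;
      int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
      for (int k = 0; k < 3; ++k) { a[k]=V(i0,k); b[k]=V(i1,k); c[k]=V(i2,k); }
      closest_on_tri(p, a, b, c, q);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) { double dd = q[k]-p[k]; d2 += dd*dd; }
      if (d2 < bestd2) {
        bestd2 = d2; bestf = f;
        best[0]=q[0]; best[1]=q[1]; best[2]=q[2];
      }
    }
    cp(i,0)=best[0]; cp(i,1)=best[1]; cp(i,2)=best[2];
    dist[i] = std::sqrt(bestd2);
    face[i] = bestf + 1;
    prevf = bestf;
  }
  return List::create(_["point"]=cp, _["distance"]=dist, _["face"]=face);
}

// Generalized winding number of each query point with respect to the closed
// mesh (V, F): ~1 inside, ~0 outside. Solid angle via van Oosterom-Strackee.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix points, NumericMatrix V, IntegerMatrix F) {
  int np = points.nrow(), nf = F.nrow();
  NumericVector w(np);
  for (int i = 0; i < np; ++i) {
    double px = points(i,0), py = points(i,1), pz = points(i,2);
    double total = 0.0;
    for (int f = 0; f < nf; ++f) {
      int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
      double ax = V(i0,0)-px, ay = V(i0,1)-py, az = V(i0,2)-pz;
      double bx = V(i1,0)-px, by = V(i1,1)-py, bz = V(i1,2)-pz;
      double cx2 = V(i2,0)-px, cy2 = V(i2,1)-py, cz2 = V(i2,2)-pz;
      double la = std::sqrt(ax*ax+ay*ay+az*az);
      double lb = std::sqrt(bx*bx+by*by+bz*bz);
      double lc = std::sqrt(cx2*cx2+cy2*cy2+cz2*cz2);
      double num = ax*(by*cz2 - bz*cy2) - ay*(bx*cz2 - bz*cx2) + az*(bx*cy2 - by*cx2);
      double den = la*lb*lc + (ax*bx+ay*by+az*bz)*lc +
                   (bx*cx2+by*cy2+bz*cz2)*la + (cx2*ax+cy2*ay+cz2*az)*lb;
      total += 2.0 * std::atan2(num, den);
    }
    w[i] = total / (4.0 * M_PI);
  }
  return w;
}
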