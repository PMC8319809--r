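#include <Rcpp.h>
#include <vector>
#include <cfloat>
using namespace Rcpp;

// Nearest distance from query points to a triangle mesh, with the nearest
// surface point returned (needed to decide whether a contact sits on the
// pillar apex cap or the sidewall). Brute force over faces with a cheap
// per-face bounding-box rejection against the current best distance.

static inline void closest_on_tri(const double p[3], const double a[3],
                                  const double b[3], const double c[3],
                                  double out[3]) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i] = a[i] + v*ab[i];
    return;
  }
  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i] = a[i] + w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i] = b[i] + w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// [[Rcpp::export(name = ".points_to_mesh")]]
List points_to_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix nearest(np, 3);
  IntegerVector nearest_face(np);

  // face bounding boxes
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  std::vector<double> tv(9 * nf);
  for (int t = 0; t < nf; ++t) {
    for (int c = 0; c < 3; ++c) {
      int vi = F(t, c) - 1;
      for (int a = 0; a < 3; ++a) tv[9*t + 3*c + a] = V(vi, a);
    }
    for (int a = 0; a < 3; ++a) {
      double lo = tv[9*t+a], hi = lo;
      for (int c = 1; c < 3; ++c) {
        double x = tv[9*t + 3*c + a];
        if (x < lo) lo = x;
        if (x > hi) hi = x;
      }
      blo[3*t+a] = lo; bhi[3*t+a] = hi;
    }
  }

  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double best = DBL_MAX, bp[3] = {0,0,0};
    int bface = 0;
    for (int t = 0; t < nf; ++t) {
      // bbox lower bound on distance^2
      double lb = 0.0;
      for (int a = 0; a < 3; ++a) {
        double d = 0.0;
        if (p[a] < blo[3*t+a]) d = blo[3*t+a] - p[a];
        else if (p[a] > bhi[3*t+a]) d = p[a] - bhi[3*t+a];
        lb += d * d;
      }
      if (lb >= best) continue;
      double q[3];
      closest_on_tri(p, &tv[9*t], &tv[9*t+3], &tv[9*t+6], q);
      double d2 = 0.0;
      for (int a = 0; a < 3; ++a) { double d = p[a]-q[a]; d2 += d*d; }
      if (d2 < best) { best = d2; bp[0]=q[0]; bp[1]=q[1]; bp[2]=q[2]; bface = t; }
    }
    dist[i] = std::sqrt(best);
    nearest(i,0)=bp[0]; nearest(i,1)=bp[1]; nearest(i,2)=bp[2];
    nearest_face[i] = bface + 1;
  }
  return List::create(_["distance"] = dist, _["nearest"] = nearest,
                      _["face"] = nearest_face);
}
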