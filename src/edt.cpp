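#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm run separably along each axis with the axis'
// physical sample spacing). Input: integer mask (nonzero = inside). Output:
// for every inside voxel the Euclidean distance (same units as spacing) to
// the centre of the nearest outside voxel; 0 on outside voxels. Voxels beyond
// the grid border are treated as outside by the R wrapper (zero padding).

// squared distances in nm^2 stay far below BIG, so BIG acts as "no seed here"
// without the NaNs that true infinities produce in the envelope intersections
static const double BIG = 1e30;

static void dt1d(const std::vector<double> &g, std::vector<double> &out,
                 int n, double s) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double fq = g[q];
    double sdash;
    while (true) {
      double fv = g[v[k]];
      sdash = ((fq + s2 * q * q) - (fv + s2 * (double)v[k] * v[k])) /
              (2.0 * s2 * (q - v[k]));
      if (sdash <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = sdash; z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double d = s * (q - v[j]);
    out[q] = d * d + g[v[j]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericVector D(mask.size());
  const int *m = INTEGER(mask);
  double *dd = REAL(D);
  R_xlen_t n = mask.size();
  for (R_xlen_t i = 0; i < n; ++i) dd[i] = m[i] ? BIG : 0.0;

  auto idx = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
  };

  std::vector<double> line, out;
  // axis 1
  line.resize(d1); out.resize(d1);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      bool any = false;
      for (int i = 0; i < d1; ++i) { line[i] = dd[idx(i,j,k)]; if (line[i] != 0.0) any = true; }
      if (!any) continue;
      dt1d(line, out, d1, spacing[0]);
      for (int i = 0; i < d1; ++i) dd[idx(i,j,k)] = out[i];
    }
  // axis 2
  line.resize(d2); out.resize(d2);
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      bool any = false;
      for (int j = 0; j < d2; ++j) { line[j] = dd[idx(i,j,k)]; if (line[j] != 0.0) any = true; }
      if (!any) continue;
      dt1d(line, out, d2, spacing[1]);
      for (int j = 0; j < d2; ++j) dd[idx(i,j,k)] = out[j];
    }
  // axis 3
  line.resize(d3); out.resize(d3);
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      bool any = false;
      for (int k = 0; k < d3; ++k) { line[k] = dd[idx(i,j,k)]; if (line[k] != 0.0) any = true; }
      if (!any) continue;
      dt1d(line, out, d3, spacing[2]);
      for (int k = 0; k < d3; ++k) dd[idx(i,j,k)] = out[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) dd[i] = std::sqrt(dd[i]);
  D.attr("dim") = dim;
  return D;
}
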