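#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable 3D convolution with one odd-length kernel applied along each
// axis (edge replication). Used to anti-alias binary masks before
// isosurfacing and for light denoising.

// [[Rcpp::export(name = ".sepconv3")]]
NumericVector sepconv3(NumericVector img, NumericVector kernel) {
  IntegerVector dim = img.attr("dim");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int kn = kernel.size(), kh = kn / 2;
  NumericVector a(clone(img)), b(img.size());
  double *src = REAL(a), *dst = REAL(b);
  const double *kw = REAL(kernel);

  auto idx = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
  };
  int dims[3] = {d1, d2, d3};

  for (int axis = 0; axis < 3; ++axis) {
    int n = dims[axis];
    for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      int pos[3] = {i, j, k};
      double acc = 0.0;
      for (int t = -kh; t <= kh; ++t) {
        int p[3] = {pos[0], pos[1], pos[2]};
        p[axis] = std::min(std::max(pos[axis] + t, 0), n - 1);
        acc += kw[t + kh] * src[idx(p[0], p[1], p[2])];
      }
      dst[idx(i, j, k)] = acc;
    }
    std::swap(src, dst);
  }
  // after 3 passes the result sits in src's buffer
  NumericVector out = (src == REAL(a)) ? a : b;
  out.attr("dim") = dim;
  return out;
}
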