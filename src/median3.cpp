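#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 3x3x3 median filter with edge replication; the standard edge-preserving
// speckle suppressor applied before multi-level thresholding.

// [[Rcpp::export(name = ".median3")]]
NumericVector median3(NumericVector img) {
  IntegerVector dim = img.attr("dim");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double *in = REAL(img);
  NumericVector res(img.size());
  double *out = REAL(res);
  double w[27];

  auto idx = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
  };

  for (int k = 0; k < d3; ++k)
  for (int j = 0; j < d2; ++j)
  for (int i = 0; i < d1; ++i) {
    int n = 0;
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = std::min(std::max(k + dk, 0), d3 - 1);
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), d2 - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), d1 - 1);
          w[n++] = in[idx(ii, jj, kk)];
        }
      }
    }
    std::nth_element(w, w + 13, w + 27);
    out[idx(i, j, k)] = w[13];
  }
  res.attr("dim") = dim;
  return res;
}
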