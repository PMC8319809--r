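#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D binary mask (nonzero = foreground)
// with 6- or 26-connectivity. Components are numbered 1..K in raster-scan
// order of their first-seen voxel; relabelling by size is done in R.

// [[Rcpp::export(name = ".cc3d")]]
IntegerVector cc3d(IntegerVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int *m = INTEGER(mask);
  IntegerVector lab(mask.size());
  int *L = INTEGER(lab);
  const R_xlen_t n = mask.size();
  for (R_xlen_t i = 0; i < n; ++i) L[i] = 0;

  std::vector<int> off;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(di); off.push_back(dj); off.push_back(dk);
      }
  const int noff = (int)off.size() / 3;

  std::vector<R_xlen_t> stack;
  int comp = 0;
  for (int k = 0; k < d3; ++k)
  for (int j = 0; j < d2; ++j)
  for (int i = 0; i < d1; ++i) {
    R_xlen_t p = (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
    if (!m[p] || L[p]) continue;
    ++comp;
    L[p] = comp;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      int qi = (int)(q % d1);
      int qj = (int)((q / d1) % d2);
      int qk = (int)(q / ((R_xlen_t)d1 * d2));
      for (int o = 0; o < noff; ++o) {
        int ni = qi + off[3*o], nj = qj + off[3*o+1], nk = qk + off[3*o+2];
        if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3) continue;
        R_xlen_t np = (R_xlen_t)ni + (R_xlen_t)d1 * ((R_xlen_t)nj + (R_xlen_t)d2 * nk);
        if (m[np] && !L[np]) { L[np] = comp; stack.push_back(np); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
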