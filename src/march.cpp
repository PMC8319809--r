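#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Isosurface of a 3D scalar field by marching tetrahedra on the
// Kuhn/Freudenthal 6-tetrahedron decomposition of each grid cell.
// The decomposition is identical in every cell, so the induced triangulation
// of shared cell faces agrees across neighbours and the extracted surface of
// any bounded region is closed by construction. Nodes sit at voxel centres;
// vertex v of an intersected tet edge is placed by linear interpolation and
// shared between tets through a global edge key, so the mesh is watertight
// (every edge on exactly two faces) whenever the >level region does not touch
// the grid border (callers zero-pad first).

static inline double node_pos(int idx, double sp) { return idx * sp; }

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, NumericVector spacing, double level) {
  IntegerVector dim = field.attr("dim");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const double *f = REAL(field);
  const uint64_t nnodes = (uint64_t)d1 * d2 * d3;

  // 6 tets per cell; corners encoded as (o1,o2,o3) offsets in {0,1}
  static const int tets[6][4][3] = {
    {{0,0,0},{1,0,0},{1,1,0},{1,1,1}},
    {{0,0,0},{1,0,0},{1,0,1},{1,1,1}},
    {{0,0,0},{0,1,0},{1,1,0},{1,1,1}},
    {{0,0,0},{0,1,0},{0,1,1},{1,1,1}},
    {{0,0,0},{0,0,1},{1,0,1},{1,1,1}},
    {{0,0,0},{0,0,1},{0,1,1},{1,1,1}}
  };

  std::unordered_map<uint64_t,int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  auto lin = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)d1 * ((uint64_t)j + (uint64_t)d2 * k);
  };

  // returns 0-based vertex id for the iso point on edge (ga, gb)
  auto edge_point = [&](uint64_t ga, uint64_t gb, double fa_, double fb_,
                        const double pa[3], const double pb[3]) -> int {
    uint64_t lo = ga < gb ? ga : gb, hi = ga < gb ? gb : ga;
    uint64_t key = lo * nnodes + hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa_) / (fb_ - fa_);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  };

  int ci[4][3];          // corner indices of current tet
  double cf[4], cp[4][3]; // corner values / positions
  uint64_t cg[4];

  for (int k = 0; k + 1 < d3; ++k)
  for (int j = 0; j + 1 < d2; ++j)
  for (int i = 0; i + 1 < d1; ++i) {
    // quick reject: all 8 corners on one side
    bool any_in = false, any_out = false;
    for (int o = 0; o < 8; ++o) {
      int oi = o & 1, oj = (o >> 1) & 1, ok = (o >> 2) & 1;
      double v = f[lin(i + oi, j + oj, k + ok)];
      if (v > level) any_in = true; else any_out = true;
    }
    if (!any_in || !any_out) continue;

    for (int t = 0; t < 6; ++t) {
      int inside_mask = 0;
      for (int c = 0; c < 4; ++c) {
        ci[c][0] = i + tets[t][c][0];
        ci[c][1] = j + tets[t][c][1];
        ci[c][2] = k + tets[t][c][2];
        cg[c] = lin(ci[c][0], ci[c][1], ci[c][2]);
        cf[c] = f[cg[c]];
        cp[c][0] = node_pos(ci[c][0], s1);
        cp[c][1] = node_pos(ci[c][1], s2);
        cp[c][2] = node_pos(ci[c][2], s3);
        if (cf[c] > level) inside_mask |= (1 << c);
      }
      if (inside_mask == 0 || inside_mask == 15) continue;

      int nin = __builtin_popcount(inside_mask);
      int ins[4], outs[4], ni = 0, no = 0;
      for (int c = 0; c < 4; ++c)
        if (inside_mask & (1 << c)) ins[ni++] = c; else outs[no++] = c;

      // reference direction: inside centroid -> outside centroid
      double gin[3] = {0,0,0}, gout[3] = {0,0,0};
      for (int c = 0; c < ni; ++c)
        for (int a = 0; a < 3; ++a) gin[a] += cp[ins[c]][a] / ni;
      for (int c = 0; c < no; ++c)
        for (int a = 0; a < 3; ++a) gout[a] += cp[outs[c]][a] / no;
      double dir[3] = {gout[0]-gin[0], gout[1]-gin[1], gout[2]-gin[2]};

      auto emit = [&](int va, int vb, int vc) {
        // orient so the normal points from inside to outside
        double e1[3], e2[3], n[3];
        double ax = vx[va], ay = vy[va], az = vz[va];
        e1[0] = vx[vb]-ax; e1[1] = vy[vb]-ay; e1[2] = vz[vb]-az;
        e2[0] = vx[vc]-ax; e2[1] = vy[vc]-ay; e2[2] = vz[vc]-az;
        n[0] = e1[1]*e2[2]-e1[2]*e2[1];
        n[1] = e1[2]*e2[0]-e1[0]*e2[2];
        n[2] = e1[0]*e2[1]-e1[1]*e2[0];
        double d = n[0]*dir[0]+n[1]*dir[1]+n[2]*dir[2];
        if (d >= 0) { fa.push_back(va); fb.push_back(vb); fc.push_back(vc); }
        else        { fa.push_back(va); fb.push_back(vc); fc.push_back(vb); }
      };

      if (nin == 1 || nin == 3) {
        int apex = (nin == 1) ? ins[0] : outs[0];
        int oth[3], m = 0;
        for (int c = 0; c < 4; ++c) if (c != apex) oth[m++] = c;
        int e0 = edge_point(cg[apex], cg[oth[0]], cf[apex], cf[oth[0]], cp[apex], cp[oth[0]]);
        int e1 = edge_point(cg[apex], cg[oth[1]], cf[apex], cf[oth[1]], cp[apex], cp[oth[1]]);
        int e2 = edge_point(cg[apex], cg[oth[2]], cf[apex], cf[oth[2]], cp[apex], cp[oth[2]]);
        emit(e0, e1, e2);
      } else { // nin == 2: quad split into two triangles
        int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
        int eac = edge_point(cg[a], cg[c], cf[a], cf[c], cp[a], cp[c]);
        int ead = edge_point(cg[a], cg[d], cf[a], cf[d], cp[a], cp[d]);
        int ebd = edge_point(cg[b], cg[d], cf[b], cf[d], cp[b], cp[d]);
        int ebc = edge_point(cg[b], cg[c], cf[b], cf[c], cp[b], cp[c]);
        emit(eac, ead, ebd);
        emit(eac, ebd, ebc);
      }
    }
  }

  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0)=vx[v]; V(v,1)=vy[v]; V(v,2)=vz[v]; }
  IntegerMatrix F(nf, 3);
  for (int t = 0; t < nf; ++t) { F(t,0)=fa[t]+1; F(t,1)=fb[t]+1; F(t,2)=fc[t]+1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
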