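#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Isosurface of a binary indicator field at level 0.5, via marching
// tetrahedra on the Freudenthal (6-tetrahedra) decomposition of each grid
// cube. The decomposition is translation-consistent — shared cube faces
// carry the same diagonal in both neighbouring cubes — so the extracted
// surface is watertight by construction, and every triangle is oriented
// with its normal pointing away from the inside region. Surface vertices
// lie at midpoints of bipolar tetrahedron edges (the midpoint is exact for
// a 0/1 field at iso-level 0.5). The field is implicitly zero-padded so
// surfaces close at the grid boundary.
//
// Field values are point samples at voxel centres; point (i, j, k)
// (0-based, padded range -1..n) sits at origin + (i, j, k) * spacing.

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::unordered_map<uint64_t, int> edge_vertex;
};

// [[Rcpp::export(name = ".marching_tets")]]
List marching_tets(LogicalVector field, IntegerVector dims,
                   NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = nx + 2, py = ny + 2;  // padded grid for point ids

  auto inside = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    return field[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  auto point_id = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)(i + 1) +
           (uint64_t)px * ((uint64_t)(j + 1) + (uint64_t)py * (uint64_t)(k + 1));
  };

  MeshAcc m;

  auto coord = [&](const int p[3], double out[3]) {
    for (int c = 0; c < 3; ++c) out[c] = origin[c] + p[c] * spacing[c];
  };

  // welded vertex at the midpoint of the edge between grid points a and b
  auto edge_vert = [&](const int a[3], const int b[3]) -> int {
    uint64_t ia = point_id(a[0], a[1], a[2]), ib = point_id(b[0], b[1], b[2]);
    uint64_t key = ia < ib ? (ia << 32) | ib : (ib << 32) | ia;
    auto it = m.edge_vertex.find(key);
    if (it != m.edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    coord(a, pa); coord(b, pb);
    m.vx.push_back(0.5 * (pa[0] + pb[0]));
    m.vy.push_back(0.5 * (pa[1] + pb[1]));
    m.vz.push_back(0.5 * (pa[2] + pb[2]));
    int id = (int)m.vx.size();  // 1-based
    m.edge_vertex.emplace(key, id);
    return id;
  };

  // emit triangle (va, vb, vc), flipping if needed so the normal points away
  // from the strictly-inside reference point `ref`
  auto emit = [&](int va, int vb, int vc, const double ref[3]) {
    const double ax = m.vx[va - 1], ay = m.vy[va - 1], az = m.vz[va - 1];
    const double bx = m.vx[vb - 1], by = m.vy[vb - 1], bz = m.vz[vb - 1];
    const double cx = m.vx[vc - 1], cy = m.vy[vc - 1], cz = m.vz[vc - 1];
    const double u0 = bx - ax, u1 = by - ay, u2 = bz - az;
    const double v0 = cx - ax, v1 = cy - ay, v2 = cz - az;
    const double n0 = u1 * v2 - u2 * v1;
    const double n1 = u2 * v0 - u0 * v2;
    const double n2 = u0 * v1 - u1 * v0;
    const double gx = (ax + bx + cx) / 3 - ref[0];
    const double gy = (ay + by + cy) / 3 - ref[1];
    const double gz = (az + bz + cz) / 3 - ref[2];
    m.fa.push_back(va);
    if (n0 * gx + n1 * gy + n2 * gz >= 0) {
      m.fb.push_back(vb); m.fc.push_back(vc);
    } else {
      m.fb.push_back(vc); m.fc.push_back(vb);
    }
  };

  // Freudenthal tetrahedra: paths from corner 0 to corner 7 of the unit
  // cube, corners indexed x + 2y + 4z.
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  static const int CORNER[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        bool in[8];
        int any = 0, all = 1;
        for (int c = 0; c < 8; ++c) {
          in[c] = inside(i + CORNER[c][0], j + CORNER[c][1], k + CORNER[c][2]);
          any |= in[c]; all &= in[c];
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int tin[4], tout[4], nin = 0, nout = 0;
          int tp[4][3];
          for (int c = 0; c < 4; ++c) {
            const int cc = TETS[t][c];
            tp[c][0] = i + CORNER[cc][0];
            tp[c][1] = j + CORNER[cc][1];
            tp[c][2] = k + CORNER[cc][2];
            if (in[cc]) tin[nin++] = c; else tout[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          double ref[3];
          coord(tp[tin[0]], ref);
          if (nin == 1) {
            const int a = tin[0];
            emit(edge_vert(tp[a], tp[tout[0]]),
                 edge_vert(tp[a], tp[tout[1]]),
                 edge_vert(tp[a], tp[tout[2]]), ref);
          } else if (nin == 3) {
            const int d = tout[0];
            emit(edge_vert(tp[d], tp[tin[0]]),
                 edge_vert(tp[d], tp[tin[1]]),
                 edge_vert(tp[d], tp[tin[2]]), ref);
          } else {
            const int a = tin[0], b = tin[1], c = tout[0], d = tout[1];
            const int mac = edge_vert(tp[a], tp[c]);
            const int mad = edge_vert(tp[a], tp[d]);
            const int mbd = edge_vert(tp[b], tp[d]);
            const int mbc = edge_vert(tp[b], tp[c]);
            emit(mac, mad, mbd, ref);
            emit(mac, mbd, mbc, ref);
          }
        }
      }

  NumericMatrix V(m.vx.size(), 3);
  for (size_t r = 0; r < m.vx.size(); ++r) {
    V(r, 0) = m.vx[r]; V(r, 1) = m.vy[r]; V(r, 2) = m.vz[r];
  }
  IntegerMatrix F(m.fa.size(), 3);
  for (size_t r = 0; r < m.fa.size(); ++r) {
    F(r, 0) = m.fa[r]; F(r, 1) = m.fb[r]; F(r, 2) = m.fc[r];
  }
  return List::create(Named("vertices") = V, Named("faces") = F);
}
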