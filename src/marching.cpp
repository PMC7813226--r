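#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// decomposition of each cell. The decomposition is translation-invariant and
// face-consistent between neighbouring cells, so the extracted surface of any
// zero-padded binary field is closed and 2-manifold (no ambiguous cases, in
// contrast to the classic 256-entry cube table).
//
// field: numeric vector, R array dim (nz, ny, nx), z fastest.
// Cell corners sit at voxel centres; a corner is inside iff value > iso.
// Output vertices are (x, y, z) in 1-based voxel coordinates; faces are
// 1-based and consistently oriented with outward normals.

struct Key {
  int64_t a, b;
  bool operator==(const Key& o) const { return a == o.a && b == o.b; }
};
struct KeyHash {
  size_t operator()(const Key& k) const {
    return std::hash<int64_t>()(k.a * 1000003LL + k.b);
  }
};

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims, double iso) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  auto lin = [&](int z, int y, int x) -> int64_t {
    return (int64_t)z + (int64_t)y * nz + (int64_t)x * nz * ny;  // 0-based
  };
  // corner offsets encoded dz*4 + dy*2 + dx
  const int CDZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  const int CDY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int CDX[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  // 6 Kuhn tetrahedra: paths 0 -> 7 adding one axis bit at a time
  const int axes[6][3] = {{4, 2, 1}, {4, 1, 2}, {2, 4, 1},
                          {2, 1, 4}, {1, 4, 2}, {1, 2, 4}};
  int tets[6][4];
  for (int p = 0; p < 6; ++p) {
    tets[p][0] = 0;
    for (int s = 0; s < 3; ++s) tets[p][s + 1] = tets[p][s] | axes[p][s];
  }

  std::unordered_map<Key, int, KeyHash> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  // position of voxel (z,y,x) 0-based in (x,y,z) coordinates, 1-based coords
  auto edge_point = [&](int64_t la, int64_t lb, double va, double vb) -> int {
    Key k = la < lb ? Key{la, lb} : Key{lb, la};
    auto it = edge_vertex.find(k);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (la > lb) t = 1.0 - t;
    int64_t lo = std::min(la, lb), hi = std::max(la, lb);
    int az = lo % nz, ay = (lo / nz) % ny, ax = lo / ((int64_t)nz * ny);
    int bz = hi % nz, by = (hi / nz) % ny, bx = hi / ((int64_t)nz * ny);
    double px = (ax + 1) + t * (bx - ax);
    double py = (ay + 1) + t * (by - ay);
    double pz = (az + 1) + t * (bz - az);
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_vertex.emplace(k, id);
    return id;
  };

  auto add_tri = [&](int a, int b, int c, double rx, double ry, double rz) {
    // orient so the normal points away from the inside reference point
    double ax_ = vx[a], ay_ = vy[a], az_ = vz[a];
    double ux = vx[b] - ax_, uy = vy[b] - ay_, uz = vz[b] - az_;
    double wx = vx[c] - ax_, wy = vy[c] - ay_, wz = vz[c] - az_;
    double nxv = uy * wz - uz * wy;
    double nyv = uz * wx - ux * wz;
    double nzv = ux * wy - uy * wx;
    double cx = (ax_ + vx[b] + vx[c]) / 3.0 - rx;
    double cy = (ay_ + vy[b] + vy[c]) / 3.0 - ry;
    double cz = (az_ + vz[b] + vz[c]) / 3.0 - rz;
    if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(b, c);
    f0.push_back(a + 1); f1.push_back(b + 1); f2.push_back(c + 1);
  };

  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        double cv[8]; int64_t cl[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cl[c] = lin(z + CDZ[c], y + CDY[c], x + CDX[c]);
          cv[c] = field[cl[c]];
          (cv[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          int in[4], out[4], ni = 0, no = 0;
          for (int s = 0; s < 4; ++s) {
            int c = tets[p][s];
            if (cv[c] > iso) in[ni++] = c; else out[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          // inside reference point: mean of inside corner positions (x,y,z)
          double rx = 0, ry = 0, rz = 0;
          for (int s = 0; s < ni; ++s) {
            rx += x + CDX[in[s]] + 1; ry += y + CDY[in[s]] + 1; rz += z + CDZ[in[s]] + 1;
          }
          rx /= ni; ry /= ni; rz /= ni;
          if (ni == 1) {
            int a = edge_point(cl[in[0]], cl[out[0]], cv[in[0]], cv[out[0]]);
            int b = edge_point(cl[in[0]], cl[out[1]], cv[in[0]], cv[out[1]]);
            int c = edge_point(cl[in[0]], cl[out[2]], cv[in[0]], cv[out[2]]);
            add_tri(a, b, c, rx, ry, rz);
          } else if (ni == 3) {
            int a = edge_point(cl[in[0]], cl[out[0]], cv[in[0]], cv[out[0]]);
            int b = edge_point(cl[in[1]], cl[out[0]], cv[in[1]], cv[out[0]]);
            int c = edge_point(cl[in[2]], cl[out[0]], cv[in[2]], cv[out[0]]);
            add_tri(a, b, c, rx, ry, rz);
          } else {  // ni == 2: quad split into two triangles
            int e11 = edge_point(cl[in[0]], cl[out[0]], cv[in[0]], cv[out[0]]);
            int e12 = edge_point(cl[in[0]], cl[out[1]], cv[in[0]], cv[out[1]]);
            int e22 = edge_point(cl[in[1]], cl[out[1]], cv[in[1]], cv[out[1]]);
            int e21 = edge_point(cl[in[1]], cl[out[0]], cv[in[1]], cv[out[0]]);
            add_tri(e11, e12, e22, rx, ry, rz);
            add_tri(e11, e22, e21, rx, ry, rz);
          }
        }
      }

  int nv = vx.size(), nf = f0.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = f0[i]; faces(i, 1) = f1[i]; faces(i, 2) = f2[i];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
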