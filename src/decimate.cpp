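#include <Rcpp.h>
#include <queue>
#include <set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Quadric-error edge-collapse decimation (Garland-Heckbert style error
// metric). Candidate positions for a collapse are the two endpoints and the
// midpoint; collapses that would break the local manifold structure (link
// condition) or flip a surviving face normal are rejected. Collapsing stops
// when the alive-face count reaches the target or no legal collapse remains.

struct Quadric {
  double q[10];  // xx xy xz xd yy yz yd zz zd dd
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d) {
    q[0] += a * a; q[1] += a * b; q[2] += a * c; q[3] += a * d;
    q[4] += b * b; q[5] += b * c; q[6] += b * d;
    q[7] += c * c; q[8] += c * d; q[9] += d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
};

struct Cand {
  double cost;
  int u, v, ver_u, ver_v;
  double px, py, pz;
  bool operator<(const Cand& o) const { return cost > o.cost; }  // min-heap
};

// [[Rcpp::export(name = ".qem_decimate")]]
List qem_decimate(NumericMatrix vertices, IntegerMatrix faces, int target_faces) {
  const int nv = vertices.nrow(), nf = faces.nrow();
  std::vector<double> VX(nv), VY(nv), VZ(nv);
  for (int i = 0; i < nv; ++i) { VX[i] = vertices(i,0); VY[i] = vertices(i,1); VZ[i] = vertices(i,2); }
  std::vector<std::array<int,3>> F(nf);
  for (int i = 0; i < nf; ++i) F[i] = { faces(i,0) - 1, faces(i,1) - 1, faces(i,2) - 1 };

  std::vector<bool> v_alive(nv, true), f_alive(nf, true);
  std::vector<int> version(nv, 0);
  std::vector<std::vector<int>> vfaces(nv);
  std::vector<Quadric> Q(nv);

  auto face_normal = [&](int fi, double* n) -> double {
    const auto& f = F[fi];
    double ux = VX[f[1]]-VX[f[0]], uy = VY[f[1]]-VY[f[0]], uz = VZ[f[1]]-VZ[f[0]];
    double wx = VX[f[2]]-VX[f[0]], wy = VY[f[2]]-VY[f[0]], wz = VZ[f[2]]-VZ[f[0]];
    n[0] = uy*wz - uz*wy; n[1] = uz*wx - ux*wz; n[2] = ux*wy - uy*wx;
    double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (len > 0) { n[0]/=len; n[1]/=len; n[2]/=len; }
    return len;
  };

  for (int i = 0; i < nf; ++i) {
    double n[3];
    double len = face_normal(i, n);
    for (int s = 0; s < 3; ++s) vfaces[F[i][s]].push_back(i);
    if (len <= 0) continue;
    double d = -(n[0]*VX[F[i][0]] + n[1]*VY[F[i][0]] + n[2]*VZ[F[i][0]]);
    for (int s = 0; s < 3; ++s) Q[F[i][s]].add_plane(n[0], n[1], n[2], d);
  }

  std::priority_queue<Cand> heap;
  auto push_edge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    Quadric qq = Q[u]; qq.add(Q[v]);
    double cands[3][3] = {
      {VX[u], VY[u], VZ[u]},
      {VX[v], VY[v], VZ[v]},
      {(VX[u]+VX[v])/2, (VY[u]+VY[v])/2, (VZ[u]+VZ[v])/2}
    };
    double best = R_PosInf, bx = cands[2][0], by = cands[2][1], bz = cands[2][2];
    for (int c = 0; c < 3; ++c) {
      double e = qq.eval(cands[c][0], cands[c][1], cands[c][2]);
      if (e < best) { best = e; bx = cands[c][0]; by = cands[c][1]; bz = cands[c][2]; }
    }
    heap.push({best, u, v, version[u], version[v], bx, by, bz});
  };

  {
    std::set<std::pair<int,int>> edges;
    for (int i = 0; i < nf; ++i)
      for (int s = 0; s < 3; ++s) {
        int a = F[i][s], b = F[i][(s+1)%3];
        if (a > b) std::swap(a, b);
        edges.insert({a, b});
      }
    for (auto& e : edges) push_edge(e.first, e.second);
  }

  int alive_faces = nf;
  auto nbrs = [&](int u) {
    std::set<int> out;
    for (int fi : vfaces[u]) if (f_alive[fi])
      for (int s = 0; s < 3; ++s) if (F[fi][s] != u) out.insert(F[fi][s]);
    return out;
  };

  while (alive_faces > target_faces && !heap.empty()) {
    Cand c = heap.top(); heap.pop();
    int u = c.u, v = c.v;
    if (!v_alive[u] || !v_alive[v]) continue;
    if (version[u] != c.ver_u || version[v] != c.ver_v) continue;

    std::vector<int> shared;
    for (int fi : vfaces[u]) if (f_alive[fi]) {
      const auto& f = F[fi];
      if (f[0] == v || f[1] == v || f[2] == v) shared.push_back(fi);
    }
    if (shared.empty()) continue;  // stale: no longer an edge

    // link condition: common neighbours must be exactly the third vertices
    // of the shared faces
    std::set<int> nu = nbrs(u), nv2 = nbrs(v), common, third;
    std::set_intersection(nu.begin(), nu.end(), nv2.begin(), nv2.end(),
                          std::inserter(common, common.begin()));
    for (int fi : shared)
      for (int s = 0; s < 3; ++s)
        if (F[fi][s] != u && F[fi][s] != v) third.insert(F[fi][s]);
    if (common != third) continue;

    // normal-flip / degeneracy check on surviving faces of u and v
    double oldx_u = VX[u], oldy_u = VY[u], oldz_u = VZ[u];
    double oldx_v = VX[v], oldy_v = VY[v], oldz_v = VZ[v];
    bool reject = false;
    for (int w : {u, v}) {
      for (int fi : vfaces[w]) {
        if (!f_alive[fi]) continue;
        bool is_shared = false;
        for (int fs : shared) if (fs == fi) { is_shared = true; break; }
        if (is_shared) continue;
        double n0[3];
        if (face_normal(fi, n0) <= 0) continue;
        VX[u] = VX[v] = c.px; VY[u] = VY[v] = c.py; VZ[u] = VZ[v] = c.pz;
        double n1[3];
        double len1 = face_normal(fi, n1);
        VX[u] = oldx_u; VY[u] = oldy_u; VZ[u] = oldz_u;
        VX[v] = oldx_v; VY[v] = oldy_v; VZ[v] = oldz_v;
        if (len1 <= 1e-12 || n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2] < 0) {
          reject = true; break;
        }
      }
      if (reject) break;
    }
    if (reject) continue;

    // collapse v into u at the candidate position
    VX[u] = c.px; VY[u] = c.py; VZ[u] = c.pz;
    Q[u].add(Q[v]);
    for (int fi : shared) { f_alive[fi] = false; --alive_faces; }
    for (int fi : vfaces[v]) {
      if (!f_alive[fi]) continue;
      for (int s = 0; s < 3; ++s) if (F[fi][s] == v) F[fi][s] = u;
      vfaces[u].push_back(fi);
    }
    v_alive[v] = false;
    ++version[u]; ++version[v];
    for (int w : nbrs(u)) push_edge(u, w);
  }

  // compact output
  std::vector<int> remap(nv, -1);
  std::vector<double> ox, oy, oz;
  std::vector<std::array<int,3>> of;
  for (int i = 0; i < nf; ++i) {
    if (!f_alive[i]) continue;
    std::array<int,3> f;
    for (int s = 0; s < 3; ++s) {
      int vtx = F[i][s];
      if (remap[vtx] < 0) {
        remap[vtx] = ox.size();
        ox.push_back(VX[vtx]); oy.push_back(VY[vtx]); oz.push_back(VZ[vtx]);
      }
      f[s] = remap[vtx] + 1;
    }
    of.push_back(f);
  }
  NumericMatrix verts(ox.size(), 3);
  for (size_t i = 0; i < ox.size(); ++i) { verts(i,0)=ox[i]; verts(i,1)=oy[i]; verts(i,2)=oz[i]; }
  IntegerMatrix fmat(of.size(), 3);
  for (size_t i = 0; i < of.size(); ++i) { fmat(i,0)=of[i][0]; fmat(i,1)=of[i][1]; fmat(i,2)=of[i][2]; }
  return List::create(_["vertices"] = verts, _["faces"] = fmat);
}
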