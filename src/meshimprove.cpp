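// Local mesh improvement: damped Laplacian smoothing of interior nodes plus
// Lawson edge flips, applied only in the neighbourhood of low-quality
// elements (steep-wall transition zones).  Boundary nodes never move and
// boundary edges are never flipped, so tags remain valid.  Deterministic:
// fixed sweep order, fixed pass budget.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline double tri_area(const std::vector<double>& x, const std::vector<double>& y,
                       int a, int b, int c) {
  return 0.5 * ((x[b] - x[a]) * (y[c] - y[a]) - (y[b] - y[a]) * (x[c] - x[a]));
}

double tri_min_angle(const std::vector<double>& x, const std::vector<double>& y,
                     int a, int b, int c) {
  double ax = x[b] - x[a], ay = y[b] - y[a];
  double bx = x[c] - x[b], by = y[c] - y[b];
  double cx = x[a] - x[c], cy = y[a] - y[c];
  double la = std::hypot(ax, ay), lb = std::hypot(bx, by), lc = std::hypot(cx, cy);
  double A = std::acos(std::min(1.0, std::max(-1.0, (lb * lb + lc * lc - la * la) / (2 * lb * lc))));
  double B = std::acos(std::min(1.0, std::max(-1.0, (la * la + lc * lc - lb * lb) / (2 * la * lc))));
  double C = M_PI - A - B;
  return std::min(A, std::min(B, C));
}

} // namespace

// [[Rcpp::export]]
List mesh_improve(NumericMatrix nodes, IntegerMatrix tris,
                  LogicalVector boundary_node, double angle_floor_deg,
                  int max_passes) {
  const int nn = nodes.nrow(), nt = tris.nrow();
  const double floor_rad = angle_floor_deg * M_PI / 180.0;
  std::vector<double> x(nn), y(nn);
  for (int i = 0; i < nn; ++i) { x[i] = nodes(i, 0); y[i] = nodes(i, 1); }
  std::vector<int> t(3 * nt);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j) t[3 * i + j] = tris(i, j) - 1;

  for (int pass = 0; pass < max_passes; ++pass) {
    // flag cells below the floor and collect their 1-ring node neighbourhood
    std::vector<char> node_active(nn, 0);
    int nbad = 0;
    for (int i = 0; i < nt; ++i) {
      if (tri_min_angle(x, y, t[3 * i], t[3 * i + 1], t[3 * i + 2]) < floor_rad) {
        ++nbad;
        for (int j = 0; j < 3; ++j) node_active[t[3 * i + j]] = 1;
      }
    }
    if (nbad == 0) break;
    // expand one ring
    std::vector<char> grow(node_active);
    for (int i = 0; i < nt; ++i) {
      bool any = node_active[t[3 * i]] || node_active[t[3 * i + 1]] ||
                 node_active[t[3 * i + 2]];
      if (any) for (int j = 0; j < 3; ++j) grow[t[3 * i + j]] = 1;
    }
    node_active.swap(grow);

    // node -> incident triangles
    std::vector<std::vector<int> > ntri(nn);
    for (int i = 0; i < nt; ++i)
      for (int j = 0; j < 3; ++j) ntri[t[3 * i + j]].push_back(i);

    // damped Laplacian smoothing with inversion/quality guard
    for (int v = 0; v < nn; ++v) {
      if (!node_active[v] || boundary_node[v]) continue;
      double sx = 0, sy = 0; int cnt = 0;
      for (size_t k = 0; k < ntri[v].size(); ++k) {
        int i = ntri[v][k];
        for (int j = 0; j < 3; ++j) {
          int w = t[3 * i + j];
          if (w != v) { sx += x[w]; sy += y[w]; ++cnt; }
        }
      }
      if (!cnt) continue;
      double ox = x[v], oy = y[v];
      double qx = ox + 0.5 * (sx / cnt - ox);
      double qy = oy + 0.5 * (sy / cnt - oy);
      double before = M_PI, after = M_PI;
      for (size_t k = 0; k < ntri[v].size(); ++k) {
        int i = ntri[v][k];
        before = std::min(before, tri_min_angle(x, y, t[3 * i], t[3 * i + 1], t[3 * i + 2]));
      }
      x[v] = qx; y[v] = qy;
      bool ok = true;
      for (size_t k = 0; k < ntri[v].size() && ok; ++k) {
        int i = ntri[v][k];
        if (tri_area(x, y, t[3 * i], t[3 * i + 1], t[3 * i + 2]) <= 0) ok = false;
        after = std::min(after, tri_min_angle(x, y, t[3 * i], t[3 * i + 1], t[3 * i + 2]));
      }
      if (!ok || after < before) { x[v] = ox; y[v] = oy; }
    }

    // Lawson flips on interior edges touching the active set
    std::unordered_map<int64_t, std::pair<int, int> > edge_tris;
    edge_tris.reserve(3 * nt);
    for (int i = 0; i < nt; ++i) {
      for (int j = 0; j < 3; ++j) {
        int a = t[3 * i + j], b = t[3 * i + (j + 1) % 3];
        int64_t key = (int64_t)std::min(a, b) * nn + std::max(a, b);
        auto it = edge_tris.find(key);
        if (it == edge_tris.end()) edge_tris[key] = std::make_pair(i, -1);
        else it->second.second = i;
      }
    }
    std::vector<int64_t> keys;
    keys.reserve(edge_tris.size());
    for (auto& kv : edge_tris) if (kv.second.second >= 0) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    for (size_t ki = 0; ki < keys.size(); ++ki) {
      auto pr = edge_tris[keys[ki]];
      int i1 = pr.first, i2 = pr.second;
      if (i1 < 0 || i2 < 0) continue;
      int a = (int)(keys[ki] / nn), b = (int)(keys[ki] % nn);
      if (!node_active[a] && !node_active[b]) continue;
      // skip if an earlier flip already removed this edge from either triangle
      int hits = 0;
      for (int j = 0; j < 3; ++j) {
        if (t[3 * i1 + j] == a || t[3 * i1 + j] == b) ++hits;
        if (t[3 * i2 + j] == a || t[3 * i2 + j] == b) ++hits;
      }
      if (hits != 4) continue;
      // opposite vertices
      int c = -1, d = -1;
      for (int j = 0; j < 3; ++j) {
        int w = t[3 * i1 + j];
        if (w != a && w != b) c = w;
        w = t[3 * i2 + j];
        if (w != a && w != b) d = w;
      }
      if (c < 0 || d < 0 || c == d) continue;
      // current and flipped configurations must both be valid (convex quad)
      double q_now = std::min(
          tri_min_angle(x, y, t[3 * i1], t[3 * i1 + 1], t[3 * i1 + 2]),
          tri_min_angle(x, y, t[3 * i2], t[3 * i2 + 1], t[3 * i2 + 2]));
      // orient the candidate triangles (c, d, a) / (d, c, b) consistently
      double a1 = tri_area(x, y, c, a, d), a2 = tri_area(x, y, d, b, c);
      if (a1 <= 0 || a2 <= 0) continue;
      double q_new = std::min(tri_min_angle(x, y, c, a, d),
                              tri_min_angle(x, y, d, b, c));
      if (q_new > q_now + 1e-12) {
        t[3 * i1] = c; t[3 * i1 + 1] = a; t[3 * i1 + 2] = d;
        t[3 * i2] = d; t[3 * i2 + 1] = b; t[3 * i2 + 2] = c;
        // refresh adjacency lazily: rebuild on next pass; mark edges stale by
        // removing them from this sweep
        edge_tris[keys[ki]] = std::make_pair(-1, -1);
      }
    }
  }

  NumericMatrix nodes_out(nn, 2);
  for (int i = 0; i < nn; ++i) { nodes_out(i, 0) = x[i]; nodes_out(i, 1) = y[i]; }
  IntegerMatrix tris_out(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j) tris_out(i, j) = t[3 * i + j] + 1;
  return List::create(_["nodes"] = nodes_out, _["triangles"] = tris_out);
}
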