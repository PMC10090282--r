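#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Fixed-radius connected components via spatial grid hashing + union-find.
// Two points are connected iff their Euclidean distance is <= radius; the
// grid cell size equals the radius, so all candidate pairs are found in the
// 3x3x3 cell neighborhood.

namespace {

struct UF {
  std::vector<int> parent;
  explicit UF(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

inline int64_t cellKey(int ix, int iy, int iz) {
  // pack 21 bits per axis with offset; field scenes are far below the limit
  const int64_t off = 1 << 20;
  return (((int64_t)(ix + off)) << 42) | (((int64_t)(iy + off)) << 21) |
         ((int64_t)(iz + off));
}

} // namespace

// [[Rcpp::export(name = ".radiusComponents")]]
IntegerVector radiusComponents(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  IntegerVector comp(n);
  if (n == 0) return comp;
  const double r2 = radius * radius;
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(pts(i, 0) / radius);
    cy[i] = (int)std::floor(pts(i, 1) / radius);
    cz[i] = (int)std::floor(pts(i, 2) / radius);
    grid[cellKey(cx[i], cy[i], cz[i])].push_back(i);
  }
  UF uf(n);
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cellKey(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = pts(i, 0) - pts(j, 0);
            double ddy = pts(i, 1) - pts(j, 1);
            double ddz = pts(i, 2) - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) uf.unite(i, j);
          }
        }
  }
  for (int i = 0; i < n; ++i) comp[i] = uf.find(i);
  return comp; // root index per point (0-based); relabeling happens in R
}
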