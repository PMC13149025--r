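// Grid-indexed DBSCAN for 3D point sets.
//
// Classic algorithm (Ester et al. expansion with a FIFO seed queue), with
// region queries served by a uniform grid of cell size eps. The epsilon
// neighbourhood COUNT INCLUDES THE QUERY POINT itself (sklearn convention).
// Points are processed in input order and seeds appended in input order, so
// labels are deterministic for a given input ordering.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <deque>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices
  const int64_t B = 1 << 20;
  return ((int64_t)(ix + B) << 42) | ((int64_t)(iy + B) << 21) |
         (int64_t)(iz + B);
}

// [[Rcpp::export(name = ".dbscan3d_cpp")]]
IntegerVector dbscan3d_cpp(NumericMatrix pts, double eps, int minpts) {
  const int n = pts.nrow();
  IntegerVector labels(n, 0);         // 0 = noise / unassigned
  if (n == 0) return labels;
  const double eps2 = eps * eps;

  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(pts(i, 0) / eps);
    cy[i] = (int)std::floor(pts(i, 1) / eps);
    cz[i] = (int)std::floor(pts(i, 2) / eps);
    grid[cell_key(cx[i], cy[i], cz[i])].push_back(i);
  }

  std::vector<int> nb;
  auto region_query = [&](int i) {
    nb.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double d0 = pts(i, 0) - pts(j, 0);
            double d1 = pts(i, 1) - pts(j, 1);
            double d2 = pts(i, 2) - pts(j, 2);
            if (d0 * d0 + d1 * d1 + d2 * d2 <= eps2) nb.push_back(j);
          }
        }
  };

  std::vector<char> visited(n, 0);
  int cluster = 0;
  std::deque<int> seeds;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    region_query(i);
    if ((int)nb.size() < minpts) continue;  // noise (may become border later)
    ++cluster;
    labels[i] = cluster;
    seeds.assign(nb.begin(), nb.end());
    while (!seeds.empty()) {
      int q = seeds.front(); seeds.pop_front();
      if (labels[q] == 0) labels[q] = cluster;  // claim border/noise point
      if (visited[q]) continue;
      visited[q] = 1;
      labels[q] = cluster;
      region_query(q);
      if ((int)nb.size() >= minpts)
        for (int j : nb) if (!visited[j] || labels[j] == 0) seeds.push_back(j);
    }
  }
  return labels;
}
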