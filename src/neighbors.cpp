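// Spatial neighbor primitives used by the segmentation stage: exact
// k-nearest-neighbor mean distances and exact single-linkage Euclidean
// components, both over a voxel hash grid.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Grid {
  double h;
  double minx, miny, minz;
  long long ny, nz;
  std::unordered_map<long long, std::vector<int>> cells;

  Grid(const NumericMatrix &pts, double cell) : h(cell) {
    const int n = pts.nrow();
    minx = miny = minz = R_PosInf;
    double maxx = R_NegInf, maxy = R_NegInf, maxz = R_NegInf;
    for (int i = 0; i < n; ++i) {
      minx = std::min(minx, pts(i, 0)); maxx = std::max(maxx, pts(i, 0));
      miny = std::min(miny, pts(i, 1)); maxy = std::max(maxy, pts(i, 1));
      minz = std::min(minz, pts(i, 2)); maxz = std::max(maxz, pts(i, 2));
    }
    ny = (long long)std::floor((maxy - miny) / h) + 3;
    nz = (long long)std::floor((maxz - minz) / h) + 3;
    cells.reserve(n);
    for (int i = 0; i < n; ++i) cells[key(pts(i, 0), pts(i, 1),
                                          pts(i, 2))].push_back(i);
  }
  long long key(double x, double y, double z) const {
    long long ix = (long long)std::floor((x - minx) / h);
    long long iy = (long long)std::floor((y - miny) / h);
    long long iz = (long long)std::floor((z - minz) / h);
    return (ix * ny + iy) * nz + iz;
  }
  long long keyIdx(long long ix, long long iy, long long iz) const {
    return (ix * ny + iy) * nz + iz;
  }
  void cellOf(double x, double y, double z, long long &ix, long long &iy,
              long long &iz) const {
    ix = (long long)std::floor((x - minx) / h);
    iy = (long long)std::floor((y - miny) / h);
    iz = (long long)std::floor((z - minz) / h);
  }
};

inline double sqdist(const NumericMatrix &p, int i, int j) {
  const double dx = p(i, 0) - p(j, 0), dy = p(i, 1) - p(j, 1),
               dz = p(i, 2) - p(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// Mean distance of every point to its k nearest neighbors (exact).
// Cell size is chosen from the typical point spacing; the shell search
// expands until the k-th best distance is certified complete.
// [[Rcpp::export(name = ".knnMeanDistanceCpp")]]
NumericVector knnMeanDistanceCpp(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (n <= k) stop("need more points than k");
  // spacing estimate from the bounding box of a 2D-ish surface cloud
  double minx = R_PosInf, maxx = R_NegInf, miny = R_PosInf,
         maxy = R_NegInf, minz = R_PosInf, maxz = R_NegInf;
  for (int i = 0; i < n; ++i) {
    minx = std::min(minx, pts(i, 0)); maxx = std::max(maxx, pts(i, 0));
    miny = std::min(miny, pts(i, 1)); maxy = std::max(maxy, pts(i, 1));
    minz = std::min(minz, pts(i, 2)); maxz = std::max(maxz, pts(i, 2));
  }
  double span = std::max({maxx - minx, maxy - miny, maxz - minz, 1e-6});
  double h = 2.0 * span / std::max(1.0, std::sqrt((double)n));
  Grid grid(pts, h);

  NumericVector out(n);
  std::vector<double> best;
  for (int i = 0; i < n; ++i) {
    long long cx, cy, cz;
    grid.cellOf(pts(i, 0), pts(i, 1), pts(i, 2), cx, cy, cz);
    best.clear();
    int shell = 1;
    for (;; ++shell) {
      // gather candidates from the (2*shell+1)^3 block once per growth
      best.clear();
      for (long long ix = cx - shell; ix <= cx + shell; ++ix)
        for (long long iy = cy - shell; iy <= cy + shell; ++iy)
          for (long long iz = cz - shell; iz <= cz + shell; ++iz) {
            auto it = grid.cells.find(grid.keyIdx(ix, iy, iz));
            if (it == grid.cells.end()) continue;
            for (int j : it->second)
              if (j != i) best.push_back(sqdist(pts, i, j));
          }
      if ((int)best.size() >= k) {
        std::nth_element(best.begin(), best.begin() + (k - 1),
                         best.end());
        double kth = std::sqrt(best[k - 1]);
        if (kth <= shell * h || shell > 64) break;
      }
      if (shell > 64) break;   // degenerate spread; accept what we have
    }
    int kk = std::min<int>(k, best.size());
    std::partial_sort(best.begin(), best.begin() + kk, best.end());
    double acc = 0;
    for (int t = 0; t < kk; ++t) acc += std::sqrt(best[t]);
    out[i] = kk > 0 ? acc / kk : R_PosInf;
  }
  return out;
}

// Exact single-linkage connected components with linkage radius r.
// Voxels of edge r; two points within r are always in the same or
// adjacent voxels, so a BFS over 26-neighbor voxel pairs with an exact
// minimum-distance check gives exact single linkage. Component labels
// are numbered by first appearance in point order.
// [[Rcpp::export(name = ".euclideanComponentsCpp")]]
IntegerVector euclideanComponentsCpp(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  IntegerVector lab(n, 0);
  if (n == 0) return lab;
  Grid grid(pts, radius);
  const double r2 = radius * radius * (1.0 + 1e-12) + 1e-300;

  // voxel list and index
  std::vector<const std::vector<int> *> vox;
  std::unordered_map<long long, int> vidx;
  std::vector<long long> vkey;
  vox.reserve(grid.cells.size());
  for (auto &kv : grid.cells) {
    vidx[kv.first] = (int)vox.size();
    vkey.push_back(kv.first);
    vox.push_back(&kv.second);
  }
  const int nv = (int)vox.size();
  std::vector<int> vcomp(nv, 0);

  // decode voxel key to coordinates for neighbor lookup
  auto decode = [&](long long key, long long &ix, long long &iy,
                    long long &iz) {
    iz = key % grid.nz; long long rest = key / grid.nz;
    if (iz < 0) { iz += grid.nz; rest -= 1; }
    iy = rest % grid.ny; ix = rest / grid.ny;
    if (iy < 0) { iy += grid.ny; ix -= 1; }
  };
  auto linked = [&](int a, int b) {
    for (int i : *vox[a])
      for (int j : *vox[b])
        if (sqdist(pts, i, j) <= r2) return true;
    return false;
  };

  int cur = 0;
  std::queue<int> queue;
  // seed components in point order so labels are deterministic
  for (int p = 0; p < n; ++p) {
    long long cx, cy, cz;
    grid.cellOf(pts(p, 0), pts(p, 1), pts(p, 2), cx, cy, cz);
    int v0 = vidx[grid.keyIdx(cx, cy, cz)];
    if (vcomp[v0] != 0) continue;
    vcomp[v0] = ++cur;
    queue.push(v0);
    while (!queue.empty()) {
      int v = queue.front(); queue.pop();
      long long ix, iy, iz;
      decode(vkey[v], ix, iy, iz);
      for (long long dx = -1; dx <= 1; ++dx)
        for (long long dy = -1; dy <= 1; ++dy)
          for (long long dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            auto it = vidx.find(grid.keyIdx(ix + dx, iy + dy, iz + dz));
            if (it == vidx.end() || vcomp[it->second] != 0) continue;
            if (linked(v, it->second)) {
              vcomp[it->second] = cur;
              queue.push(it->second);
            }
          }
    }
  }
  for (int v = 0; v < nv; ++v)
    for (int i : *vox[v]) lab[i] = vcomp[v];
  // renumber by first appearance
  std::unordered_map<int, int> seen;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    auto it = seen.find(lab[i]);
    if (it == seen.end()) { seen[lab[i]] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
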