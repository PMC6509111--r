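#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <numeric>
#include <cmath>
using namespace Rcpp;

static inline int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement of a nonnegative statistic volume.
// Thresholds are the midpoints h = (k - 0.5) * dh, k = 1..n_steps; at each
// threshold every suprathreshold voxel accrues extent^E * h^H * dh, where
// extent is the size of its connected component under the given connectivity.
// Voxels are activated in descending order with a union-find, so the whole
// pass costs O(n_steps * V) plus near-linear merging.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim,
                       double E, double H, double dh, int n_steps,
                       int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int V = nx * ny * nz;
  if (stat.size() != V) stop("stat length does not match dim");
  if (dh <= 0) stop("dh must be positive");

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({{dx, dy, dz}});
      }

  std::vector<int> ord(V);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(V), csize(V, 0);
  std::iota(parent.begin(), parent.end(), 0);
  std::vector<char> active(V, 0);
  std::vector<int> actlist;
  actlist.reserve(V);
  NumericVector out(V);

  int p = 0;
  for (int step = n_steps; step >= 1; --step) {
    double h = (step - 0.5) * dh;
    while (p < V && stat[ord[p]] >= h) {
      int v = ord[p++];
      active[v] = 1;
      csize[v] = 1;
      actlist.push_back(v);
      int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
      for (const auto &o : offs) {
        int X = x + o[0], Y = y + o[1], Z = z + o[2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int w = X + nx * (Y + ny * Z);
        if (!active[w]) continue;
        int rv = find_root(parent, v), rw = find_root(parent, w);
        if (rv != rw) {
          if (csize[rv] < csize[rw]) std::swap(rv, rw);
          parent[rw] = rv;
          csize[rv] += csize[rw];
        }
      }
    }
    if (actlist.empty()) continue;
    double hH = std::pow(h, H) * dh;
    for (int v : actlist) {
      int r = find_root(parent, v);
      out[v] += std::pow((double)csize[r], E) * hH;
    }
  }
  return out;
}
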