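#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Build searchlight neighborhoods: for every in-mask voxel, the 1-based
// linear indices of in-mask voxels whose integer-lattice offset lies within
// the supplied sphere (offsets: k x 3, voxel units, includes the origin).
// [[Rcpp::export]]
List sl_build_cpp(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int V = nx * ny * nz;
  if (mask.size() != V) stop("mask length does not match dim");
  std::vector<int> centers;
  List nbrs(V);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = x + nx * (y + ny * z);
        if (!mask[v]) continue;
        std::vector<int> nb;
        nb.reserve(offsets.nrow());
        for (int k = 0; k < offsets.nrow(); ++k) {
          int X = x + offsets(k, 0), Y = y + offsets(k, 1), Z = z + offsets(k, 2);
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          int w = X + nx * (Y + ny * Z);
          if (mask[w]) nb.push_back(w + 1);
        }
        centers.push_back(v + 1);
        nbrs[v] = wrap(nb);
      }
  return List::create(_["centers"] = wrap(centers), _["neighbors"] = nbrs);
}

// Per-target mean within-target correlation distance at each searchlight
// center. data: V x C matrix of beta values; group: 0-based target index per
// condition. Conditions with zero variance in a neighborhood are dropped
// there; centers losing more than max_drop_frac of conditions, or with fewer
// than min_voxels neighbors, yield NA for every target.
// [[Rcpp::export]]
NumericMatrix sl_distinct_cpp(NumericMatrix data, List neighbors,
                              IntegerVector centers, IntegerVector group,
                              int n_groups, int min_voxels,
                              double max_drop_frac) {
  const int V = data.nrow(), C = data.ncol();
  NumericMatrix out(V, n_groups);
  std::fill(out.begin(), out.end(), NA_REAL);
  IntegerVector skipped(V);

  std::vector<double> cx(C), norms(C);
  std::vector<char> ok(C);
  std::vector<double> buf;  // centered patterns, nb-major per condition

  for (int ci = 0; ci < centers.size(); ++ci) {
    int v = centers[ci] - 1;
    IntegerVector nb = neighbors[v];
    const int m = nb.size();
    if (m < min_voxels) { skipped[v] = 1; continue; }
    buf.assign((size_t)m * C, 0.0);
    int dropped = 0;
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += data(nb[i] - 1, c);
      double mu = s / m, ss = 0.0;
      double *col = &buf[(size_t)m * c];
      for (int i = 0; i < m; ++i) {
        double d = data(nb[i] - 1, c) - mu;
        col[i] = d;
        ss += d * d;
      }
      norms[c] = std::sqrt(ss);
      ok[c] = norms[c] > 0;
      if (!ok[c]) ++dropped;
    }
    if (dropped > max_drop_frac * C) { skipped[v] = 2; continue; }
    for (int g = 0; g < n_groups; ++g) {
      double acc = 0.0;
      int npair = 0;
      for (int a = 0; a < C; ++a) {
        if (group[a] != g || !ok[a]) continue;
        const double *ca = &buf[(size_t)m * a];
        for (int b = a + 1; b < C; ++b) {
          if (group[b] != g || !ok[b]) continue;
          const double *cb = &buf[(size_t)m * b];
          double dot = 0.0;
          for (int i = 0; i < m; ++i) dot += ca[i] * cb[i];
          acc += 1.0 - dot / (norms[a] * norms[b]);
          ++npair;
        }
      }
      if (npair > 0) out(v, g) = acc / npair;
    }
  }
  out.attr("skipped") = skipped;
  return out;
}
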