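#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling by breadth-first search over linear
// (column-major) voxel indices.  Seeds are visited in scan order, so label k
// is the component whose first voxel comes k-th in column-major order —
// a deterministic labelling independent of platform.
//
// connectivity: 6 (face neighbours) or 26 (face + edge + corner).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("`dims` must have length 3.");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims.");
  if (connectivity != 6 && connectivity != 26) {
    stop("connectivity must be 6 or 26.");
  }

  // neighbour offsets in voxel coordinates
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manhattan = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manhattan != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int n_nb = (int)dx.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    queue.clear();
    queue.push_back(seed);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t v = queue[head++];
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < n_nb; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
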