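#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Connected-component labelling of a 3-D mask by breadth-first search.
// mask: logical/integer vector in R array (column-major) order with dims
// (nx, ny, nz); connectivity 6 (faces) or 26 (faces+edges+corners).
// Labels are assigned in raster-scan order of each component's first voxel,
// so the output is fully deterministic.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector mask, IntegerVector dims,
                       int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dx);
        off.push_back(dy);
        off.push_back(dz);
      }

  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); k += 3) {
        int xx = x + off[k], yy = y + off[k + 1], zz = z + off[k + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = next;
          q.push(w);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
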