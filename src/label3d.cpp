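#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling of a binary volume, 6- or 26-connectivity.
// Iterative BFS with an explicit stack; labels are assigned in raster order
// so the result is deterministic.

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n);
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int nn = static_cast<int>(ox.size());

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (m[i] != 1 || L[i] != 0) continue;
    ++next;
    L[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cz = static_cast<int>(cur / (static_cast<R_xlen_t>(nx) * ny));
      const int rem = static_cast<int>(cur - static_cast<R_xlen_t>(cz) * nx * ny);
      const int cy = rem / nx, cx = rem % nx;
      for (int k = 0; k < nn; ++k) {
        const int x = cx + ox[k], y = cy + oy[k], z = cz + oz[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const R_xlen_t j = x + static_cast<R_xlen_t>(nx) * (y + static_cast<R_xlen_t>(ny) * z);
        if (m[j] == 1 && L[j] == 0) {
          L[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
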