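#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected component labeling of a binary mask by flood fill in raster
// order.  Component ids are assigned in order of first (i.e. minimal) linear
// voxel index, so ties between equally sized components are broken
// deterministically by comparing ids.  connectivity is 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask,
                                   int nx, int ny, int nz,
                                   int connectivity) {
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if ((connectivity == 6 && ad > 1) || (connectivity == 18 && ad > 2))
          continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nn = dxs.size();
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back(); stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / (static_cast<R_xlen_t>(nx) * ny);
      for (int k = 0; k < nn; ++k) {
        const int x2 = x + dxs[k], y2 = y + dys[k], z2 = z + dzs[k];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        const R_xlen_t w = x2 + static_cast<R_xlen_t>(nx) * (y2 + static_cast<R_xlen_t>(ny) * z2);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  lab.attr("nComponents") = next;
  return lab;
}
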