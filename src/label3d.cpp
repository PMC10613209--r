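#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a logical array by iterative flood
// fill (BFS with an explicit stack). connectivity: 6 (faces) or 26 (full).
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  // neighbor offsets as (dx,dy,dz)
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = (int)dx.size();

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int px = (int)(p % nx);
      int py = (int)((p / nx) % ny);
      int pz = (int)(p / ((R_xlen_t)nx * ny));
      for (int q = 0; q < nn; ++q) {
        int qx = px + dx[q], qy = py + dy[q], qz = pz + dz[q];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
          continue;
        R_xlen_t r = qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
        if (mask[r] && lab[r] == 0) {
          lab[r] = next;
          stack.push_back(r);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
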