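// 3D connected-component labeling (6- or 26-connectivity) by breadth-first
// search. Labels are 1..K in first-encounter (scan) order; background is 0.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  if ((size_t)mask.size() != n) stop("mask length does not match dims");

  std::vector<int> off_dx, off_dy, off_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        off_dx.push_back(dx); off_dy.push_back(dy); off_dz.push_back(dz);
      }

  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur / ((size_t)nx * ny));
      int rem = (int)(cur % ((size_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (size_t k = 0; k < off_dx.size(); ++k) {
        int xx = x + off_dx[k], yy = y + off_dy[k], zz = z + off_dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t j = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
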