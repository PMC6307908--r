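#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a logical grid stored column-major
// with dim = (nz, ny, nx).  Connectivity 6, 18 or 26 refers to voxel
// face/edge/corner adjacency; anisotropy is deliberately ignored here
// (it enters only through the voxel volume downstream).
// Labels are assigned in scan order of first encounter; callers relabel.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets (dz, dy, dx)
  std::vector<int> dz_, dy_, dx_;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dz_.push_back(dz); dy_.push_back(dy); dx_.push_back(dx);
      }
  const int nnb = (int)dz_.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nnb; ++k) {
        int zz = z + dz_[k], yy = y + dy_[k], xx = x + dx_[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
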