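#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labeling of a logical mask by iterative
// flood fill. connectivity: 6 (faces), 18 (faces+edges) or 26 (full).
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nnb = (int)dxs.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    // flood fill component
    ++cur;
    labels[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)z * nx * ny);
      int y = rem / nx;
      int x = rem - y * nx;
      for (int k = 0; k < nnb; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// One pass of the iterative multi-threshold segmentation, fused in C++:
// for t = t0, t0+inc, ... <= tmax, label the voxels with img >= t,
// and OR components whose voxel count lies in [lo, hi] into the union.
// [[Rcpp::export(name = ".iter_union_cpp")]]
LogicalVector iter_union_cpp(NumericVector img, IntegerVector dims,
                             double t0, double inc, double tmax,
                             double lo, double hi, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (img.size() != n) stop("image length does not match dims");
  if (inc <= 0) stop("threshold increment must be positive");

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nnb = (int)dxs.size();

  LogicalVector uni(n, false);
  std::vector<int> labels(n);
  std::vector<R_xlen_t> stack, comp;

  for (double t = t0; t <= tmax; t += inc) {
    std::fill(labels.begin(), labels.end(), 0);
    int cur = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (img[i] < t || labels[i] != 0) continue;
      ++cur;
      labels[i] = cur;
      stack.clear(); comp.clear();
      stack.push_back(i); comp.push_back(i);
      while (!stack.empty()) {
        R_xlen_t v = stack.back();
        stack.pop_back();
        int z = (int)(v / ((R_xlen_t)nx * ny));
        int rem = (int)(v - (R_xlen_t)z * nx * ny);
        int y = rem / nx;
        int x = rem - y * nx;
        for (int k = 0; k < nnb; ++k) {
          int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
          if (img[w] >= t && labels[w] == 0) {
            labels[w] = cur;
            stack.push_back(w);
            comp.push_back(w);
          }
        }
      }
      double sz = (double)comp.size();
      if (sz >= lo && sz <= hi) {
        for (R_xlen_t w : comp) uni[w] = true;
      }
    }
  }
  return uni;
}
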