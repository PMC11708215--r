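#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D logical mask stored as a LogicalVector
// with dim = c(nz, ny, nx). connectivity = 26 (faces+edges+corners) or
// 6 (faces only). Labels are assigned in raster-scan order of first contact,
// background = 0. BFS flood fill, iterative so deep components cannot
// overflow the stack.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dz.size();

  std::vector<R_xlen_t> queue;
  int next_label = 0;
  // column-major index: i = z + nz*(y + ny*x)
  for (R_xlen_t x = 0; x < nx; ++x)
    for (R_xlen_t y = 0; y < ny; ++y)
      for (R_xlen_t z = 0; z < nz; ++z) {
        R_xlen_t i = z + nz * (y + (R_xlen_t)ny * x);
        if (!mask[i] || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        queue.clear();
        queue.push_back(i);
        size_t head = 0;
        while (head < queue.size()) {
          R_xlen_t cur = queue[head++];
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (int k = 0; k < nn; ++k) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = zz + nz * (yy + (R_xlen_t)ny * xx);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next_label;
              queue.push_back(j);
            }
          }
        }
      }
  labels.attr("dim") = dims;
  return labels;
}
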