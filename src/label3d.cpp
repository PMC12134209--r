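#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// 3D connected-component labeling of a logical array, 6-connectivity
// (faces only; z/y/x neighbours). Degenerate axes (size 1) make this 2D/1D
// labeling for free. Returns an integer array of the same dim: 0 background,
// 1..k component ids in first-encounter order.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");

  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::queue<R_xlen_t> q;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = next;
          q.push(w);
        }
      }
    }
  }
  return lab;
}
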