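#include <Rcpp.h>
using namespace Rcpp;

// Binary dilation of a 3D logical array by an explicit offset list
// (k x 3 integer matrix of dz, dy, dx). Out-of-bounds targets are clipped.
// [[Rcpp::export(name = ".dilate3d_cpp")]]
LogicalVector dilate3d_cpp(LogicalVector mask, IntegerVector dim,
                           IntegerMatrix offsets) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  LogicalVector out = clone(mask);
  out.attr("dim") = dim;
  const int k = offsets.nrow();
  for (R_xlen_t v = 0; v < n; ++v) {
    if (mask[v] != TRUE) continue;
    int z = (int)(v % nz);
    int y = (int)((v / nz) % ny);
    int x = (int)(v / ((R_xlen_t)nz * ny));
    for (int j = 0; j < k; ++j) {
      int zz = z + offsets(j, 0), yy = y + offsets(j, 1), xx = x + offsets(j, 2);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      out[(R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] = TRUE;
    }
  }
  return out;
}

// Binary erosion: a voxel survives iff it and all its offset neighbours are
// foreground; neighbours outside the array count as background, so the mask
// retreats from the array border.
// [[Rcpp::export(name = ".erode3d_cpp")]]
LogicalVector erode3d_cpp(LogicalVector mask, IntegerVector dim,
                          IntegerMatrix offsets) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  LogicalVector out(n, FALSE);
  out.attr("dim") = dim;
  const int k = offsets.nrow();
  for (R_xlen_t v = 0; v < n; ++v) {
    if (mask[v] != TRUE) continue;
    int z = (int)(v % nz);
    int y = (int)((v / nz) % ny);
    int x = (int)(v / ((R_xlen_t)nz * ny));
    bool keep = true;
    for (int j = 0; j < k && keep; ++j) {
      int zz = z + offsets(j, 0), yy = y + offsets(j, 1), xx = x + offsets(j, 2);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
        keep = false;
      } else if (mask[(R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] != TRUE) {
        keep = false;
      }
    }
    if (keep) out[v] = TRUE;
  }
  return out;
}
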