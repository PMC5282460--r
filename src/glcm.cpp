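#include <Rcpp.h>
using namespace Rcpp;

// Count co-occurrences of quantized levels at displacement (dx, dy, dz).
// q: levels 0..ng-1, laid out as an R array [y, x, z] (column-major:
// index = y + ny*x + ny*nx*z). mask: logical [y, x], applied to both
// endpoints at every band. Returns the ng x ng count table with rows =
// level at p, columns = level at p + (dx, dy, dz).
// [[Rcpp::export(name = ".glcm_count_pairs")]]
IntegerMatrix glcm_count_pairs(IntegerVector q, LogicalVector mask,
                               int ny, int nx, int nz,
                               int dx, int dy, int dz, int ng) {
  IntegerMatrix out(ng, ng);
  const int *qp = INTEGER(q);
  const int *mp = LOGICAL(mask);
  for (int z = 0; z < nz; ++z) {
    int z2 = z + dz;
    if (z2 < 0 || z2 >= nz) continue;
    R_xlen_t zoff = (R_xlen_t)ny * nx * z;
    R_xlen_t zoff2 = (R_xlen_t)ny * nx * z2;
    for (int x = 0; x < nx; ++x) {
      int x2 = x + dx;
      if (x2 < 0 || x2 >= nx) continue;
      R_xlen_t xoff = (R_xlen_t)ny * x;
      R_xlen_t xoff2 = (R_xlen_t)ny * x2;
      int ylo = dy < 0 ? -dy : 0;
      int yhi = dy > 0 ? ny - dy : ny;
      for (int y = ylo; y < yhi; ++y) {
        int y2 = y + dy;
        if (!mp[xoff + y] || !mp[xoff2 + y2]) continue;
        int i = qp[zoff + xoff + y];
        int j = qp[zoff2 + xoff2 + y2];
        out(i, j) += 1;
      }
    }
  }
  return out;
}
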