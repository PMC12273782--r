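#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize capsules (cylinders with hemispherical caps) onto a voxel grid:
// a voxel is set when its center lies within `radius` of the segment.
// Coordinates are physical (um); voxel center of index i (1-based in R,
// passed 0-based here) is origin + i * spacing.
// [[Rcpp::export]]
LogicalVector rasterize_tubes_cpp(NumericMatrix starts, NumericMatrix ends,
                                  NumericVector radii, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = FALSE;

  const int nseg = starts.nrow();
  for (int s = 0; s < nseg; ++s) {
    double ax = starts(s, 0), ay = starts(s, 1), az = starts(s, 2);
    double bx = ends(s, 0), by = ends(s, 1), bz = ends(s, 2);
    double r = radii[s];
    double lo[3], hi[3];
    lo[0] = std::min(ax, bx) - r; hi[0] = std::max(ax, bx) + r;
    lo[1] = std::min(ay, by) - r; hi[1] = std::max(ay, by) + r;
    lo[2] = std::min(az, bz) - r; hi[2] = std::max(az, bz) + r;
    int i0[3], i1[3];
    for (int a = 0; a < 3; ++a) {
      i0[a] = (int)std::floor((lo[a] - origin[a]) / spacing[a]);
      i1[a] = (int)std::ceil((hi[a] - origin[a]) / spacing[a]);
      int dmax = a == 0 ? d1 : (a == 1 ? d2 : d3);
      if (i0[a] < 0) i0[a] = 0;
      if (i1[a] > dmax - 1) i1[a] = dmax - 1;
    }
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    double r2 = r * r;
    for (int k = i0[2]; k <= i1[2]; ++k) {
      double pz = origin[2] + k * spacing[2];
      for (int j = i0[1]; j <= i1[1]; ++j) {
        double py = origin[1] + j * spacing[1];
        for (int i = i0[0]; i <= i1[0]; ++i) {
          double px = origin[0] + i * spacing[0];
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double t = L2 > 0 ? (wx * ux + wy * uy + wz * uz) / L2 : 0.0;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = TRUE;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
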