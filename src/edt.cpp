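#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact anisotropic squared Euclidean distance transform,
// Felzenszwalb & Huttenlocher lower-envelope-of-parabolas, one pass per axis.
// f: squared distances sampled along a line with physical step w (so the
// parabola rooted at sample i is w2*(q-i)^2 + f[i]).
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      if (f[v[k]] == INF) { // previous parabola is everywhere above
        if (k == 0) { k = -1; break; }
        --k;
        continue;
      }
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        if (k == 0) { k = -1; break; }
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = (f[v[k]] == INF) ? INF : w2 * dq * dq + f[v[k]];
  }
}

// Distance (in physical units given by spacing) from every voxel to the
// nearest voxel where mask is FALSE. Background voxels get 0; if the mask is
// all TRUE every distance is Inf.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest varying)
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      bool any = false;
      for (int i = 0; i < d1; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, d1, w2);
      for (int i = 0; i < d1; ++i) out[base + i] = d[i];
    }
  // axis 2
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * d2 * k;
      bool any = false;
      for (int j = 0; j < d2; ++j) { f[j] = out[base + (R_xlen_t)d1 * j]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, d2, w2);
      for (int j = 0; j < d2; ++j) out[base + (R_xlen_t)d1 * j] = d[j];
    }
  // axis 3
  w2 = spacing[2] * spacing[2];
  const R_xlen_t stride3 = (R_xlen_t)d1 * d2;
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * j;
      bool any = false;
      for (int k = 0; k < d3; ++k) { f[k] = out[base + stride3 * k]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, d3, w2);
      for (int k = 0; k < d3; ++k) out[base + stride3 * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] < INF) out[i] = std::sqrt(out[i]);
  return out;
}
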