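#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur, reflect (symmetric) boundary. sigma in voxels.
static void blur_axis(std::vector<double> &vol, int d1, int d2, int d3,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.5 * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> ker(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; ++t) {
    ker[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + radius];
  }
  for (double &k : ker) k /= s;

  int len = axis == 0 ? d1 : (axis == 1 ? d2 : d3);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)d1 : (R_xlen_t)d1 * d2);
  std::vector<double> line(len), res(len);
  auto reflect = [&](int i) {
    while (i < 0 || i >= len) {
      if (i < 0) i = -i - 1;
      if (i >= len) i = 2 * len - i - 1;
    }
    return i;
  };
  int n2 = axis == 0 ? d2 : d1;
  int n3 = axis == 2 ? d2 : d3;
  for (int b = 0; b < n3; ++b)
    for (int a = 0; a < n2; ++a) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)d1 * (a + (R_xlen_t)d2 * b);
      else if (axis == 1) base = a + (R_xlen_t)d1 * d2 * b;
      else base = a + (R_xlen_t)d1 * b; // b over d2, a over d1
      for (int i = 0; i < len; ++i) line[i] = vol[base + stride * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int t = -radius; t <= radius; ++t)
          acc += ker[t + radius] * line[reflect(i + t)];
        res[i] = acc;
      }
      for (int i = 0; i < len; ++i) vol[base + stride * i] = res[i];
    }
}

// eigenvalues of a symmetric 3x3 matrix, closed form
static void sym_eig3(double a11, double a22, double a33,
                     double a12, double a13, double a23,
                     double eig[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0) {
    eig[0] = a11; eig[1] = a22; eig[2] = a33;
    return;
  }
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
              (a33 - q) * (a33 - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13);
  double r = detB / 2.0;
  if (r < -1) r = -1;
  if (r > 1) r = 1;
  double phi = std::acos(r) / 3.0;
  double e1 = q + 2.0 * p * std::cos(phi);
  double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  double e2 = 3.0 * q - e1 - e3;
  eig[0] = e1; eig[1] = e2; eig[2] = e3;
}

// Single-scale Frangi vesselness. sigma_um is the physical Gaussian scale;
// second derivatives are gamma=1 scale-normalized (multiplied by sigma^2).
// c_param <= 0 requests the data-adaptive default: half the maximum
// Frobenius Hessian norm S over the volume at this scale.
// [[Rcpp::export]]
NumericVector frangi_scale_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector spacing, double sigma_um,
                               double alpha, double beta, double c_param,
                               bool bright_tubes) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> sm(n);
  for (R_xlen_t i = 0; i < n; ++i) sm[i] = vol[i];
  blur_axis(sm, d1, d2, d3, 0, sigma_um / spacing[0]);
  blur_axis(sm, d1, d2, d3, 1, sigma_um / spacing[1]);
  blur_axis(sm, d1, d2, d3, 2, sigma_um / spacing[2]);

  auto clampAt = [&](int i, int j, int k) -> double {
    if (i < 0) i = 0; if (i >= d1) i = d1 - 1;
    if (j < 0) j = 0; if (j >= d2) j = d2 - 1;
    if (k < 0) k = 0; if (k >= d3) k = d3 - 1;
    return sm[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
  };

  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const double g = sigma_um * sigma_um; // gamma = 1 normalization
  NumericVector ra2(n), rb2(n), ss2(n);
  std::vector<char> bright(n);
  double smax = 0;

  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t s = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        double c0 = sm[s];
        double h11 = g * (clampAt(i - 1, j, k) - 2 * c0 + clampAt(i + 1, j, k)) / (s1 * s1);
        double h22 = g * (clampAt(i, j - 1, k) - 2 * c0 + clampAt(i, j + 1, k)) / (s2 * s2);
        double h33 = g * (clampAt(i, j, k - 1) - 2 * c0 + clampAt(i, j, k + 1)) / (s3 * s3);
        double h12 = g * (clampAt(i + 1, j + 1, k) - clampAt(i + 1, j - 1, k) -
                          clampAt(i - 1, j + 1, k) + clampAt(i - 1, j - 1, k)) / (4 * s1 * s2);
        double h13 = g * (clampAt(i + 1, j, k + 1) - clampAt(i + 1, j, k - 1) -
                          clampAt(i - 1, j, k + 1) + clampAt(i - 1, j, k - 1)) / (4 * s1 * s3);
        double h23 = g * (clampAt(i, j + 1, k + 1) - clampAt(i, j + 1, k - 1) -
                          clampAt(i, j - 1, k + 1) + clampAt(i, j - 1, k - 1)) / (4 * s2 * s3);
        double eig[3];
        sym_eig3(h11, h22, h33, h12, h13, h23, eig);
        // sort by |lambda|: |l1| <= |l2| <= |l3|
        double l1 = eig[0], l2 = eig[1], l3 = eig[2], tmp;
        if (std::fabs(l1) > std::fabs(l2)) { tmp = l1; l1 = l2; l2 = tmp; }
        if (std::fabs(l2) > std::fabs(l3)) { tmp = l2; l2 = l3; l3 = tmp; }
        if (std::fabs(l1) > std::fabs(l2)) { tmp = l1; l1 = l2; l2 = tmp; }
        double a2 = std::fabs(l2), a3 = std::fabs(l3);
        ra2[s] = a3 > 0 ? (a2 * a2) / (a3 * a3) : 0.0;
        rb2[s] = (a2 * a3) > 0 ? (l1 * l1) / (a2 * a3) : 0.0;
        double S2 = l1 * l1 + l2 * l2 + l3 * l3;
        ss2[s] = S2;
        if (S2 > smax) smax = S2;
        bright[s] = bright_tubes ? (l2 < 0 && l3 < 0) : (l2 > 0 && l3 > 0);
      }

  double c = c_param > 0 ? c_param : 0.5 * std::sqrt(smax);
  double twoA2 = 2 * alpha * alpha, twoB2 = 2 * beta * beta, twoC2 = 2 * c * c;
  NumericVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!bright[s]) { out[s] = 0.0; continue; }
    double V = (1.0 - std::exp(-ra2[s] / twoA2)) *
               std::exp(-rb2[s] / twoB2) *
               (twoC2 > 0 ? (1.0 - std::exp(-ss2[s] / twoC2)) : 0.0);
    out[s] = V;
  }
  out.attr("dim") = dim;
  return out;
}
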