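#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D logical array, 6- or 26-connectivity.
// Labels are 1..ncomp in first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);

  std::vector<int> off1, off2, off3;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        off1.push_back(dx); off2.push_back(dy); off3.push_back(dz);
      }
  const int noff = (int)off1.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % d1);
      int j = (int)((cur / d1) % d2);
      int k = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int t = 0; t < noff; ++t) {
        int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
          continue;
        R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}
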