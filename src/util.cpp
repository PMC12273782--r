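#include <Rcpp.h>
using namespace Rcpp;

// Block-mean pooling over factor^3 blocks; trailing partial blocks are
// averaged over the voxels actually present.
// [[Rcpp::export]]
NumericVector block_mean_cpp(NumericVector vol, IntegerVector dim, int factor) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int o1 = (d1 + factor - 1) / factor;
  const int o2 = (d2 + factor - 1) / factor;
  const int o3 = (d3 + factor - 1) / factor;
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  for (int K = 0; K < o3; ++K)
    for (int J = 0; J < o2; ++J)
      for (int I = 0; I < o1; ++I) {
        double acc = 0;
        int cnt = 0;
        int kmax = std::min(d3, (K + 1) * factor);
        int jmax = std::min(d2, (J + 1) * factor);
        int imax = std::min(d1, (I + 1) * factor);
        for (int k = K * factor; k < kmax; ++k)
          for (int j = J * factor; j < jmax; ++j)
            for (int i = I * factor; i < imax; ++i) {
              acc += vol[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
              ++cnt;
            }
        out[I + (R_xlen_t)o1 * (J + (R_xlen_t)o2 * K)] = acc / cnt;
      }
  out.attr("dim") = IntegerVector::create(o1, o2, o3);
  return out;
}
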