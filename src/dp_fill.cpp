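#include <Rcpp.h>
using namespace Rcpp;

// Fill the composition dynamic-programming table.
//
// intensity: per-bin summed peak intensity, bins 0..L (length L+1)
// steps:     candidate predecessor offsets in bins
// residue:   1-based monosaccharide id paired with each step
//
// T[0] = 0, all other bins -inf; a bin is reachable only through a chain
// of residue steps back to bin 0. Returns the table plus back-pointers
// (predecessor bin and residue id, 0 where unreachable/none).
// [[Rcpp::export]]
List dp_fill_cpp(NumericVector intensity, IntegerVector steps,
                 IntegerVector residue) {
  const int n = intensity.size();
  const int k = steps.size();
  NumericVector T(n, R_NegInf);
  IntegerVector back_bin(n, -1);
  IntegerVector back_res(n, 0);
  T[0] = 0.0;
  for (int m = 1; m < n; ++m) {
    double best = R_NegInf;
    int bbin = -1, bres = 0;
    for (int j = 0; j < k; ++j) {
      int p = m - steps[j];
      if (p < 0) continue;
      double tp = T[p];
      if (tp > best) {
        best = tp;
        bbin = p;
        bres = residue[j];
      }
    }
    if (bbin >= 0 && best > R_NegInf) {
      T[m] = intensity[m] + best;
      back_bin[m] = bbin;
      back_res[m] = bres;
    }
  }
  return List::create(_["T"] = T, _["back_bin"] = back_bin,
                      _["back_res"] = back_res);
}
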