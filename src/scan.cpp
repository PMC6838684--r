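#include <Rcpp.h>
using namespace Rcpp;

// Best (maximum) discretized PWM score over all offsets of each window on
// one strand. `code_t` is a width x windows matrix of base codes 1..5
// (A, C, G, T, other) — transposed so each window is a contiguous column.
// `wi` is a 5 x L weight matrix whose fifth row is -Inf, so offsets covering
// ambiguous bases are skipped.
// [[Rcpp::export]]
NumericVector scan_best_scores(IntegerMatrix code_t, NumericMatrix wi) {
  const int width = code_t.nrow(), n = code_t.ncol(), L = wi.ncol();
  NumericVector best(n, R_NegInf);
  if (L > width) return best;
  const int noff = width - L + 1;
  const int *C = INTEGER(code_t);
  const double *W = REAL(wi);
  for (int i = 0; i < n; ++i) {
    const int *ci = C + static_cast<size_t>(i) * width;
    double b = R_NegInf;
    for (int o = 0; o < noff; ++o) {
      double s = 0.0;
      bool ok = true;
      for (int j = 0; j < L; ++j) {
        const double w = W[5 * j + ci[o + j] - 1];
        if (w == R_NegInf) { ok = false; break; }
        s += w;
      }
      if (ok && s > b) b = s;
    }
    best[i] = b;
  }
  return best;
}
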