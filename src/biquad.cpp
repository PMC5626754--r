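#include <Rcpp.h>
using namespace Rcpp;

// Causal cascade of second-order IIR sections (direct form II transposed is
// unnecessary here; direct form I with zero initial conditions matches the
// reference R implementation exactly).
//
// X: samples x series matrix; sections: list of list(b = c(b0,b1,b2),
// a = c(1,a1,a2)) with a normalized so a[0] == 1.
// [[Rcpp::export]]
NumericMatrix biquad_cascade(NumericMatrix X, List sections) {
  NumericMatrix Y = clone(X);
  const int n = Y.nrow(), m = Y.ncol();
  for (int s = 0; s < sections.size(); ++s) {
    List sec = sections[s];
    NumericVector b = sec["b"], a = sec["a"];
    const double b0 = b[0], b1 = b[1], b2 = b[2], a1 = a[1], a2 = a[2];
    for (int j = 0; j < m; ++j) {
      double x1 = 0, x2 = 0, y1 = 0, y2 = 0;
      for (int i = 0; i < n; ++i) {
        const double x0 = Y(i, j);
        const double y0 = b0 * x0 + b1 * x1 + b2 * x2 - a1 * y1 - a2 * y2;
        x2 = x1; x1 = x0;
        y2 = y1; y1 = y0;
        Y(i, j) = y0;
      }
    }
  }
  return Y;
}
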