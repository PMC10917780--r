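// Partitioned LD scores over a base-pair window.
// X is the n x m reference panel, columns standardized to mean 0 and
// variance 1 (1/n denominator) so that crossprod / n gives r-hat.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix ld_scores_cpp(NumericMatrix X, NumericVector pos,
                            IntegerMatrix annot, double window) {
  const int n = X.nrow(), m = X.ncol(), C = annot.ncol();
  if (pos.size() != m) stop("positions do not match panel columns");
  if (annot.nrow() != m) stop("annotation rows do not match panel columns");
  if (n < 3) stop("panel too small");
  NumericMatrix ell(m, C);

  for (int j = 0; j < m; ++j) {
    // self term: r = 1, adjusted r2 = 1
    for (int c = 0; c < C; ++c) ell(j, c) += annot(j, c);
    for (int k = j + 1; k < m && pos[k] - pos[j] <= window; ++k) {
      double dot = 0.0;
      const double *xj = &X(0, j), *xk = &X(0, k);
      for (int t = 0; t < n; ++t) dot += xj[t] * xk[t];
      const double r = dot / n;
      const double r2 = r * r;
      const double adj = r2 - (1.0 - r2) / (n - 2.0);
      for (int c = 0; c < C; ++c) {
        ell(j, c) += adj * annot(k, c);
        ell(k, c) += adj * annot(j, c);
      }
    }
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return ell;
}
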