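#include <Rcpp.h>
using namespace Rcpp;

// Row-wise argmin of d2(i, j) - w(j): the assignment step of the
// capacity-constrained power diagram. Column-major scan keeps this cache
// friendly; ties resolve to the lowest column index.
// [[Rcpp::export]]
IntegerVector pd_assign(NumericMatrix d2, NumericVector w) {
  const int n = d2.nrow(), k = d2.ncol();
  IntegerVector out(n);
  std::vector<double> best(n);
  for (int j = 0; j < k; ++j) {
    const double wj = w[j];
    const double *col = &d2(0, j);
    if (j == 0) {
      for (int i = 0; i < n; ++i) { best[i] = col[i] - wj; out[i] = 1; }
    } else {
      for (int i = 0; i < n; ++i) {
        const double v = col[i] - wj;
        if (v < best[i]) { best[i] = v; out[i] = j + 1; }
      }
    }
  }
  return out;
}
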