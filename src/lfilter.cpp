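#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR/FIR filtering with initial state.
// b, a: coefficient vectors (a[0] must be 1 after normalization in R);
// zi: initial state, length max(len(a), len(b)) - 1.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0), z(n - 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < zi.size() && i < n - 1; ++i) z[i] = zi[i];

  int m = x.size();
  NumericVector y(m);
  for (int t = 0; t < m; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (n > 1 ? z[0] : 0.0);
    for (int k = 0; k < n - 2; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    if (n > 1)
      z[n - 2] = bb[n - 1] * xt - aa[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}
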