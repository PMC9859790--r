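#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, zero initial conditions, applied
// down each column. Same semantics as the standard difference equation
//   a[0] y[n] = b[0] x[n] + ... + b[nb-1] x[n-nb+1]
//             - a[1] y[n-1] - ... - a[na-1] y[n-na+1].

// [[Rcpp::export]]
NumericMatrix df2_filter(NumericVector b, NumericVector a, NumericMatrix x) {
  int n = x.nrow(), m = x.ncol();
  int nb = b.size(), na = a.size();
  int ns = std::max(nb, na) - 1;
  NumericMatrix y(n, m);
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  for (int c = 0; c < m; ++c) {
    std::vector<double> z(ns + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      double xi = x(i, c);
      double yi = bb[0] * xi + z[0];
      for (int k = 0; k + 1 <= ns; ++k)
        z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      y(i, c) = yi;
    }
  }
  return y;
}
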