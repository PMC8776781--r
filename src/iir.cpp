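#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter; a[0] must be 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(na, nb) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i <= nz; i++) {
    bb[i] = i < nb ? b[i] : 0.0;
    aa[i] = i < na ? a[i] : 0.0;
  }
  NumericVector y(n);
  for (int i = 0; i < n; i++) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; j++)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
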