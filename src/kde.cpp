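#include <Rcpp.h>
using namespace Rcpp;

// Product-Gaussian 2-D kernel density estimate of (x, y), evaluated at
// query points (qx, qy). Exact (no binning): O(n_query * n_data).
// [[Rcpp::export(name = ".kde2d_at")]]
NumericVector kde2d_at(NumericVector x, NumericVector y,
                       NumericVector qx, NumericVector qy,
                       double hx, double hy) {
  const R_xlen_t n = x.size(), m = qx.size();
  if (y.size() != n || qy.size() != m)
    stop("coordinate vectors must have matching lengths");
  if (hx <= 0.0 || hy <= 0.0)
    stop("bandwidths must be positive");
  NumericVector out(m);
  const double norm = 1.0 / (n * hx * hy * 2.0 * M_PI);
  for (R_xlen_t j = 0; j < m; ++j) {
    double s = 0.0;
    const double qxj = qx[j], qyj = qy[j];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double u = (qxj - x[i]) / hx;
      const double v = (qyj - y[i]) / hy;
      const double e = 0.5 * (u * u + v * v);
      if (e < 40.0) s += std::exp(-e);
    }
    out[j] = s * norm;
  }
  return out;
}
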