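#include <Rcpp.h>
using namespace Rcpp;

// Single-marker OLS scan over a partitioned design matrix.
//
// The fixed part (intercept + covariates + pseudo-QTNs) is summarized by an
// orthonormal basis Q of its column span, computed once per iteration on the
// rows with non-missing phenotype. For each marker x the kernel residualizes
// x against Q (Frisch-Waugh), so the marker coefficient, its standard error
// and the residual sum of squares of the full model come from two dot
// products and a norm: O(n_eff * k) per marker, with no n x m copy and no
// per-marker factorization.
//
// mask holds 1-based row indices of phenotype-complete samples: missing
// phenotypes are handled by skipping the corresponding marker scores at test
// time rather than by subsetting (= copying) the genotype matrix.
//
// Loop order is fixed and scalar, so results are bitwise identical for any
// chunking of the marker range (parallel determinism contract).
//
// Returns per marker: effect, sxx (residualized marker sum of squares) and
// rss (full-model residual sum of squares); NA for markers that are constant
// (variance < var_tol on the masked rows) or collinear with the fixed part
// (residual norm below a relative guard). se/t/p are finished in R.
// [[Rcpp::export]]
List scan_chunk_cpp(const NumericMatrix& geno, const IntegerVector& markers,
                    const IntegerVector& mask, const NumericMatrix& Q,
                    const NumericVector& yres, const double var_tol,
                    const double collin_tol) {
  const int ne = mask.size();
  const int k = Q.ncol();
  const int nm = markers.size();
  NumericVector effect(nm, NA_REAL), sxx(nm, NA_REAL), rss(nm, NA_REAL);
  std::vector<double> x(ne);
  std::vector<double> qx(k > 0 ? k : 1);

  double yss = 0.0;
  for (int i = 0; i < ne; ++i) yss += yres[i] * yres[i];

  for (int j = 0; j < nm; ++j) {
    const int col = markers[j] - 1;
    double mean = 0.0;
    for (int i = 0; i < ne; ++i) {
      x[i] = geno(mask[i] - 1, col);
      mean += x[i];
    }
    mean /= ne;
    double css = 0.0;
    for (int i = 0; i < ne; ++i) {
      const double d = x[i] - mean;
      css += d * d;
    }
    if (ne < 2 || css / (ne - 1) < var_tol) continue;  // constant marker

    double ssq0 = 0.0;
    for (int i = 0; i < ne; ++i) ssq0 += x[i] * x[i];

    // two projection passes for numerical stability of the residual
    for (int pass = 0; pass < 2; ++pass) {
      for (int c = 0; c < k; ++c) {
        double d = 0.0;
        for (int i = 0; i < ne; ++i) d += Q(i, c) * x[i];
        qx[c] = d;
      }
      for (int c = 0; c < k; ++c) {
        const double d = qx[c];
        for (int i = 0; i < ne; ++i) x[i] -= d * Q(i, c);
      }
    }

    double s2 = 0.0, sxy = 0.0;
    for (int i = 0; i < ne; ++i) {
      s2 += x[i] * x[i];
      sxy += x[i] * yres[i];
    }
    if (s2 <= collin_tol * ssq0) continue;  // collinear with fixed part

    const double b = sxy / s2;
    double r = yss - b * sxy;
    if (r < 0.0) r = 0.0;
    effect[j] = b;
    sxx[j] = s2;
    rss[j] = r;
  }
  return List::create(_["effect"] = effect, _["sxx"] = sxx, _["rss"] = rss);
}
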