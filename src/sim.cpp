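#include <Rcpp.h>
using namespace Rcpp;

// Allele-count matrix with entry (i, j) ~ Binomial(2, f[j]), sampled by
// inverting the 3-point CDF with one unif_rand() call per entry
// (column-major order). Uses R's RNG, so draws are reproducible under
// set.seed().
// [[Rcpp::export]]
IntegerMatrix sim_binom2_matrix(const int n, const NumericVector f) {
  const int p = f.size();
  IntegerMatrix M(n, p);
  RNGScope scope;
  for (int j = 0; j < p; ++j) {
    const double fj = f[j];
    const double q0 = (1.0 - fj) * (1.0 - fj);        // P(count = 0)
    const double q01 = q0 + 2.0 * fj * (1.0 - fj);    // P(count <= 1)
    int *col = &M(0, j);
    for (int i = 0; i < n; ++i) {
      const double u = unif_rand();
      col[i] = (u > q0) + (u > q01);
    }
  }
  return M;
}

// Column-wise (m - center) / scale. NA counts propagate to NA_REAL.
// [[Rcpp::export]]
NumericMatrix standardize_matrix(const SEXP M, const NumericVector centers,
                                 const NumericVector scales) {
  if (Rf_isInteger(M)) {
    const IntegerMatrix X(M);
    const int n = X.nrow(), p = X.ncol();
    NumericMatrix Z(n, p);
    for (int j = 0; j < p; ++j) {
      const double c = centers[j], inv = 1.0 / scales[j];
      const int *src = &X(0, j);
      double *dst = &Z(0, j);
      for (int i = 0; i < n; ++i) {
        dst[i] = (src[i] == NA_INTEGER) ? NA_REAL : (src[i] - c) * inv;
      }
    }
    Z.attr("dimnames") = X.attr("dimnames");
    return Z;
  }
  const NumericMatrix X(M);
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix Z(n, p);
  for (int j = 0; j < p; ++j) {
    const double c = centers[j], inv = 1.0 / scales[j];
    const double *src = &X(0, j);
    double *dst = &Z(0, j);
    for (int i = 0; i < n; ++i) {
      dst[i] = ISNAN(src[i]) ? NA_REAL : (src[i] - c) * inv;
    }
  }
  Z.attr("dimnames") = X.attr("dimnames");
  return Z;
}

// Per-column mean and denominator-n standard deviation, skipping NAs.
// Returns a p x 3 matrix: mean, sd, number of non-missing entries.
// [[Rcpp::export]]
NumericMatrix col_mean_sd(const SEXP M) {
  const bool is_int = Rf_isInteger(M);
  const IntegerMatrix Xi = is_int ? IntegerMatrix(M) : IntegerMatrix(0, 0);
  const NumericMatrix Xd = is_int ? NumericMatrix(0, 0) : NumericMatrix(M);
  const int n = is_int ? Xi.nrow() : Xd.nrow();
  const int p = is_int ? Xi.ncol() : Xd.ncol();
  NumericMatrix out(p, 3);
  for (int j = 0; j < p; ++j) {
    double s = 0.0, s2 = 0.0;
    int m = 0;
    for (int i = 0; i < n; ++i) {
      double x;
      if (is_int) {
        const int xi = Xi(i, j);
        if (xi == NA_INTEGER) continue;
        x = xi;
      } else {
        x = Xd(i, j);
        if (ISNAN(x)) continue;
      }
      s += x;
      s2 += x * x;
      ++m;
    }
    const double mean = (m > 0) ? s / m : NA_REAL;
    double var = (m > 0) ? s2 / m - mean * mean : NA_REAL;
    if (m > 0 && var < 0) var = 0.0;  // guard rounding
    out(j, 0) = mean;
    out(j, 1) = (m > 0) ? std::sqrt(var) : NA_REAL;
    out(j, 2) = m;
  }
  return out;
}
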