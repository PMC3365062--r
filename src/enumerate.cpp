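#include <Rcpp.h>
#include <vector>
#include <cmath>

// All-subsets OLS scan over p candidate columns plus an always-included
// intercept. Works from cross-products only: for each subset the normal
// equations are solved with an in-place Cholesky factorization on small
// preallocated buffers, so cost per subset is O(k^3) flops with no heap
// allocation inside the loop.
//
//   G   : (p+1) x (p+1) cross-product of the full design, intercept first
//   gy  : cross-product of the full design with the response
//   yty : y'y
//
// Returns one row per non-empty subset (bitmask order): mask, number of
// coefficients including the intercept, residual sum of squares. RSS is
// NA if the subset cross-product is not numerically positive definite.
// [[Rcpp::export]]
Rcpp::NumericMatrix enum_subsets_rss(const Rcpp::NumericMatrix& G,
                                     const Rcpp::NumericVector& gy,
                                     double yty) {
  const int q = G.nrow();          // p + 1
  const int p = q - 1;
  if (p < 1 || p > 24) Rcpp::stop("number of candidate columns must be in 1..24");
  const unsigned long nmod = (1UL << p) - 1UL;
  Rcpp::NumericMatrix out((int) nmod, 3);
  double* o0 = &out(0, 0);
  double* o1 = &out(0, 1);
  double* o2 = &out(0, 2);

  std::vector<int> idx(q);
  std::vector<double> A(q * q);    // subset cross-product, column-major
  std::vector<double> b(q);        // subset gy, then solve workspace
  const double* Gp = G.begin();

  for (unsigned long m = 1; m <= nmod; ++m) {
    int k = 0;
    idx[k++] = 0;                  // intercept
    for (int j = 0; j < p; ++j)
      if (m & (1UL << j)) idx[k++] = j + 1;

    // gather A = G[idx, idx] (lower triangle suffices) and b = gy[idx]
    for (int c = 0; c < k; ++c) {
      const double* Gc = Gp + (size_t) idx[c] * q;
      for (int r = c; r < k; ++r) A[c * q + r] = Gc[idx[r]];
      b[c] = gy[idx[c]];
    }

    // in-place Cholesky A = L L' (lower), then solve L L' x = b
    bool ok = true;
    for (int c = 0; c < k && ok; ++c) {
      double d = A[c * q + c];
      for (int t = 0; t < c; ++t) {
        const double l = A[t * q + c];
        d -= l * l;
      }
      if (d <= 0.0 || !std::isfinite(d)) { ok = false; break; }
      const double lc = std::sqrt(d);
      A[c * q + c] = lc;
      for (int r = c + 1; r < k; ++r) {
        double s = A[c * q + r];
        for (int t = 0; t < c; ++t) s -= A[t * q + r] * A[t * q + c];
        A[c * q + r] = s / lc;
      }
    }

    double rss = NA_REAL;
    if (ok) {
      // forward solve L v = b (v overwrites b)
      double bTx = 0.0;            // b' (A^-1 b) = sum v_i^2
      for (int r = 0; r < k; ++r) {
        double s = b[r];
        for (int t = 0; t < r; ++t) s -= A[t * q + r] * b[t];
        b[r] = s / A[r * q + r];
        bTx += b[r] * b[r];
      }
      rss = yty - bTx;
      if (rss < 0.0) rss = 0.0;
    }
    o0[m - 1] = (double) m;
    o1[m - 1] = (double) k;
    o2[m - 1] = rss;
  }
  return out;
}
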