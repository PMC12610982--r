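#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Approximate entropy (classical definition, self-matches included):
// ApEn = Phi_m(r) - Phi_{m+1}(r), Chebyshev distance between embedded
// templates. Template-match counts for m and m+1 are accumulated in one
// symmetric pass over pairs, which is exact and O(N^2 (m+1)/2).
static double apen_impl(const double* x, int n, int m, double r) {
  int nt1 = n - m + 1;      // templates of length m
  int nt2 = n - m;          // templates of length m + 1
  std::vector<int> c1(nt1, 1), c2(nt2, 1);  // self-matches included
  for (int i = 0; i < nt1; ++i) {
    for (int j = i + 1; j < nt1; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      ++c1[i]; ++c1[j];
      if (i < nt2 && j < nt2 && std::fabs(x[i + m] - x[j + m]) <= r) {
        ++c2[i]; ++c2[j];
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nt1; ++i) phi1 += std::log((double)c1[i] / nt1);
  for (int i = 0; i < nt2; ++i) phi2 += std::log((double)c2[i] / nt2);
  return phi1 / nt1 - phi2 / nt2;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) stop("series too short for approximate entropy");
  if (r <= 0) return 0.0;
  return apen_impl(REAL(x), n, m, r);
}

// Per-column ApEn of a window matrix with r = r_frac * population SD of
// each column (0 when the column is constant).
// [[Rcpp::export]]
NumericVector apen_cols_cpp(NumericMatrix w, int m, double r_frac) {
  int nc = w.ncol(), nr = w.nrow();
  NumericVector out(nc);
  for (int j = 0; j < nc; ++j) {
    const double* col = &w(0, j);
    double mu = 0.0;
    for (int i = 0; i < nr; ++i) mu += col[i];
    mu /= nr;
    double ss = 0.0;
    for (int i = 0; i < nr; ++i) {
      double d = col[i] - mu;
      ss += d * d;
    }
    double sdv = std::sqrt(ss / nr);
    if (sdv <= 0.0) { out[j] = 0.0; continue; }
    out[j] = apen_impl(col, nr, m, r_frac * sdv);
  }
  return out;
}

// In-place Adam update: p -= lr * mhat / (sqrt(vhat) + eps). Buffers are
// owned exclusively by the training loop.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector p, NumericVector m, NumericVector v,
                     NumericVector g, double lr, double b1, double b2,
                     double eps, double b1c, double b2c) {
  R_xlen_t n = p.size();
  double* pp = REAL(p);
  double* pm = REAL(m);
  double* pv = REAL(v);
  double* pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / b1c) / (std::sqrt(pv[i] / b2c) + eps);
  }
}
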