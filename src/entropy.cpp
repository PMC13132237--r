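#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev distance between delay embeddings starting at i and j
// (0-based), length m, delay tau.
static inline double cheb(const NumericVector& x, int i, int j, int m,
                          int tau) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k * tau] - x[j + k * tau]);
    if (a > d) d = a;
  }
  return d;
}

// Template-pair counts for sample entropy. Both the m- and (m+1)-length
// templates range over the first n - m*tau start points so that the two
// counts are comparable (Richman & Moorman convention, generalised to a
// delay). Returns c(B, A): pairs i<j within tolerance at length m and m+1.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, int tau, double r) {
  int n = x.size();
  int nt = n - m * tau;  // number of (m+1)-templates
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = cheb(x, i, j, m, tau);
      if (d <= r) {
        B += 1.0;
        double a = std::fabs(x[i + m * tau] - x[j + m * tau]);
        if (a <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// phi_m for approximate entropy: mean over i of log(C_i) where C_i is the
// fraction of templates (self included) within tolerance r of template i.
// [[Rcpp::export]]
double apen_phi_cpp(NumericVector x, int m, int tau, double r) {
  int n = x.size();
  int nm = n - (m - 1) * tau;  // number of m-templates
  double acc = 0.0;
  for (int i = 0; i < nm; ++i) {
    int cnt = 0;
    for (int j = 0; j < nm; ++j) {
      if (cheb(x, i, j, m, tau) <= r) ++cnt;
    }
    acc += std::log((double)cnt / (double)nm);
  }
  return acc / (double)nm;
}

// Histogram of pairwise Chebyshev inter-template distances for
// distribution entropy. Bin b = min(bins-1, floor(d / max_d * bins));
// all-zero distances collapse into bin 0.
// [[Rcpp::export]]
IntegerVector disten_hist_cpp(NumericVector x, int m, int tau, int bins) {
  int n = x.size();
  int nm = n - (m - 1) * tau;
  double dmax = 0.0;
  for (int i = 0; i < nm - 1; ++i)
    for (int j = i + 1; j < nm; ++j) {
      double d = cheb(x, i, j, m, tau);
      if (d > dmax) dmax = d;
    }
  IntegerVector h(bins);
  for (int i = 0; i < nm - 1; ++i)
    for (int j = i + 1; j < nm; ++j) {
      double d = cheb(x, i, j, m, tau);
      int b = 0;
      if (dmax > 0) {
        b = (int)std::floor(d / dmax * bins);
        if (b >= bins) b = bins - 1;
      }
      h[b] += 1;
    }
  return h;
}

// Lempel-Ziv 1976 phrase count on a symbol sequence (Kaspar-Schuster
// scan). Counts the exhaustive production parsing, including a final
// incomplete phrase.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, u = 1, v = 1, vmax = 1, i = 0;
  while (u + v <= n) {
    if (s[i + v - 1] == s[u + v - 1]) {
      ++v;
    } else {
      if (v > vmax) vmax = v;
      ++i;
      if (i == u) {  // all history start points exhausted
        ++c;
        u += vmax;
        v = 1;
        i = 0;
        vmax = 1;
      } else {
        v = 1;
      }
    }
  }
  if (v != 1) ++c;
  return c;
}
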