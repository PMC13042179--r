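// O(n^2) kernels for nonlinear interval-dynamics measures.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy: pairs i<j of m-length templates
// within Chebyshev tolerance r (B), and of (m+1)-length templates (A).
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m;              // number of (m+1)-capable templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (dd <= r && dd >= 0) {
          if (std::max(d, dd) <= r) A += 1.0;
        }
      }
    }
  }
  return NumericVector::create(A, B);
}

// phi(m) for approximate entropy: mean over i of log of the fraction of
// templates within tolerance (self-matches included).
// [[Rcpp::export]]
double cpp_apen_phi(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m + 1;
  if (N < 1) return NA_REAL;
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int j = 0; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) ++cnt;
    }
    acc += std::log((double)cnt / (double)N);
  }
  return acc / (double)N;
}

// Mean exponential fuzzy membership exp(-(d/r)^2) over pairs of
// baseline-removed m-length templates.
// [[Rcpp::export]]
double cpp_fuzzy_phi(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m;
  if (N < 2) return NA_REAL;
  std::vector<double> base(N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    base[i] = s / m;
  }
  double acc = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs((x[i + k] - base[i]) - (x[j + k] - base[j]));
        if (dd > d) d = dd;
      }
      double q = d / r;
      acc += std::exp(-q * q);
    }
  }
  return 2.0 * acc / ((double)N * (N - 1));
}

// Chebyshev distances between all pairs of m-dimensional delay embeddings.
// [[Rcpp::export]]
NumericVector cpp_cheb_dists(NumericVector x, int m) {
  int n = x.size();
  int N = n - m + 1;
  if (N < 2) return NumericVector(0);
  NumericVector out((R_xlen_t)N * (N - 1) / 2);
  R_xlen_t idx = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      out[idx++] = d;
    }
  }
  return out;
}

// Full Grassberger-Procaccia slope for one embedding dimension: collects
// pair distances, picks the 5th/50th percentile scaling region, and returns
// the least-squares slope of log C(rho) vs log rho (NA when degenerate).
// [[Rcpp::export]]
double cpp_gp_slope(NumericVector x, int m) {
  int n = x.size();
  int N = n - m + 1;
  if (N < 10) return NA_REAL;
  std::vector<double> d;
  d.reserve((size_t)N * (N - 1) / 2);
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dd = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > dd) dd = a;
      }
      if (dd > 0) d.push_back(dd);
    }
  }
  if (d.size() < 20) return NA_REAL;
  size_t i05 = (size_t)(0.05 * (d.size() - 1));
  size_t i50 = (size_t)(0.50 * (d.size() - 1));
  std::nth_element(d.begin(), d.begin() + i05, d.end());
  double q05 = d[i05];
  std::nth_element(d.begin(), d.begin() + i50, d.end());
  double q50 = d[i50];
  if (q05 <= 0 || q50 <= q05) return NA_REAL;
  const int nr = 8;
  double lr0 = std::log(q05), lr1 = std::log(q50);
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int used = 0;
  for (int t = 0; t < nr; ++t) {
    double lrho = lr0 + (lr1 - lr0) * t / (nr - 1.0);
    double rho = std::exp(lrho);
    size_t cnt = 0;
    for (size_t k = 0; k < d.size(); ++k) if (d[k] <= rho) ++cnt;
    if (cnt == 0) continue;
    double lc = std::log((double)cnt / (double)d.size());
    sx += lrho; sy += lc; sxx += lrho * lrho; sxy += lrho * lc;
    ++used;
  }
  if (used < 3) return NA_REAL;
  double denom = sxx - sx * sx / used;
  if (denom <= 0) return NA_REAL;
  return (sxy - sx * sy / used) / denom;
}

// One-pass Grassberger-Procaccia slopes for all embedding dimensions
// m_min..m_max: pair distances for every m are accumulated in one sweep.
// [[Rcpp::export]]
NumericVector cpp_gp_slopes(NumericVector x, int m_min, int m_max) {
  int n = x.size();
  int nm = m_max - m_min + 1;
  NumericVector out(nm, NA_REAL);
  int N_hi = n - m_min + 1;
  if (N_hi < 12) return out;
  std::vector< std::vector<double> > dists(nm);
  for (int t = 0; t < nm; ++t)
    dists[t].reserve((size_t)N_hi * (N_hi - 1) / 2);
  for (int i = 0; i < N_hi - 1; ++i) {
    for (int j = i + 1; j < N_hi; ++j) {
      double d = 0.0;
      int kmax = m_max;
      if (i + kmax > n) kmax = n - i;
      if (j + kmax > n) kmax = n - j;
      for (int k = 0; k < kmax; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        int m = k + 1;
        if (m >= m_min && m <= m_max) {
          if (i < n - m + 1 && j < n - m + 1 && d > 0)
            dists[m - m_min].push_back(d);
        }
      }
    }
  }
  for (int t = 0; t < nm; ++t) {
    std::vector<double> &d = dists[t];
    if (d.size() < 20) continue;
    size_t i05 = (size_t)(0.05 * (d.size() - 1));
    size_t i50 = (size_t)(0.50 * (d.size() - 1));
    std::nth_element(d.begin(), d.begin() + i05, d.end());
    double q05 = d[i05];
    std::nth_element(d.begin(), d.begin() + i50, d.end());
    double q50 = d[i50];
    if (q05 <= 0 || q50 <= q05) continue;
    const int nr = 8;
    double lr0 = std::log(q05), lr1 = std::log(q50);
    double sx = 0, sy = 0, sxx = 0, sxy = 0;
    int used = 0;
    for (int u = 0; u < nr; ++u) {
      double lrho = lr0 + (lr1 - lr0) * u / (nr - 1.0);
      double rho = std::exp(lrho);
      size_t cnt = 0;
      for (size_t k = 0; k < d.size(); ++k) if (d[k] <= rho) ++cnt;
      if (cnt == 0) continue;
      double lc = std::log((double)cnt / (double)d.size());
      sx += lrho; sy += lc; sxx += lrho * lrho; sxy += lrho * lc;
      ++used;
    }
    if (used < 3) continue;
    double denom = sxx - sx * sx / used;
    if (denom <= 0) continue;
    out[t] = (sxy - sx * sy / used) / denom;
  }
  return out;
}

// Centered FIR filter (odd-length kernel), replicate-padded edges.
// [[Rcpp::export]]
NumericVector cpp_fir_centered(NumericVector x, NumericVector coef) {
  int n = x.size();
  int k = coef.size();
  int h = k / 2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < k; ++j) {
      int idx = i + j - h;
      if (idx < 0) idx = 0;
      if (idx >= n) idx = n - 1;
      acc += coef[j] * x[idx];
    }
    out[i] = acc;
  }
  return out;
}
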