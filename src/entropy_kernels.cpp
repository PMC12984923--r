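// Pairwise template-matching kernels behind the entropy bank.
// All counting conventions (index ranges, self-match handling) are fixed
// here and mirrored by the brute-force oracles in the test suite.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double cheb(const double* a, const double* b, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = std::fabs(a[k] - b[k]);
    if (v > d) d = v;
  }
  return d;
}

// Phi^m for approximate entropy: mean over i of ln C_i^m(r),
// C_i^m = (#j with Chebyshev d <= r, self included) / (N - m + 1).
// [[Rcpp::export(name = ".apen_phi_cpp")]]
double apen_phi_cpp(NumericVector x, int m, double r) {
  int n = x.size(), nt = n - m + 1;
  const double* p = REAL(x);
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j)
      if (cheb(p + i, p + j, m) <= r) ++cnt;
    acc += std::log((double)cnt / (double)nt);
  }
  return acc / (double)nt;
}

// Sample-entropy pair counts over templates i,j in 0..(N-m-1), i<j:
// B = m-length matches, A = (m+1)-length matches (self-matches excluded).
// m = 0: zero-length templates match vacuously, so B = all pairs.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size(), nt = n - m;
  const double* p = REAL(x);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = (m > 0) ? cheb(p + i, p + j, m) : 0.0;
      if (dm <= r) {
        B += 1.0;
        double d1 = std::fabs(p[i + m] - p[j + m]);
        if (d1 > dm) dm = d1;
        if (dm <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Fuzzy-entropy mean membership at dims m and m+1 on baseline-removed
// templates; exp(-(d/r)^nexp) averaged over unordered pairs among the
// common index set 0..(N-m-1).
// [[Rcpp::export(name = ".fuzzy_phis_cpp")]]
NumericVector fuzzy_phis_cpp(NumericVector x, int m, double r, double nexp) {
  int n = x.size(), nt = n - m;
  const double* p = REAL(x);
  std::vector<double> mu_m(nt), mu_m1(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += p[i + k];
    mu_m[i] = s / (double)m;
    mu_m1[i] = (s + p[i + m]) / (double)(m + 1);
  }
  double sm = 0.0, sm1 = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double v = std::fabs((p[i + k] - mu_m[i]) - (p[j + k] - mu_m[j]));
        if (v > dm) dm = v;
      }
      for (int k = 0; k <= m; ++k) {
        double v = std::fabs((p[i + k] - mu_m1[i]) - (p[j + k] - mu_m1[j]));
        if (v > dm1) dm1 = v;
      }
      sm += std::exp(-std::pow(dm / r, nexp));
      sm1 += std::exp(-std::pow(dm1 / r, nexp));
    }
  }
  double npairs = 0.5 * (double)nt * (double)(nt - 1);
  return NumericVector::create(sm / npairs, sm1 / npairs);
}

// Cross variant of apen_phi: templates of x against templates of y.
// [[Rcpp::export(name = ".cross_apen_phi_cpp")]]
double cross_apen_phi_cpp(NumericVector x, NumericVector y, int m, double r) {
  int n = x.size(), nt = n - m + 1;
  const double* px = REAL(x);
  const double* py = REAL(y);
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j)
      if (cheb(px + i, py + j, m) <= r) ++cnt;
    acc += std::log((double)cnt / (double)nt);
  }
  return acc / (double)nt;
}

// Cross sample-entropy counts over all ordered template pairs (i from x,
// j from y), i,j in 0..(N-m-1); i == j allowed (different signals).
// [[Rcpp::export(name = ".cross_sampen_counts_cpp")]]
NumericVector cross_sampen_counts_cpp(NumericVector x, NumericVector y,
                                      int m, double r) {
  int n = x.size(), nt = n - m;
  const double* px = REAL(x);
  const double* py = REAL(y);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < nt; ++j) {
      double dm = (m > 0) ? cheb(px + i, py + j, m) : 0.0;
      if (dm <= r) {
        B += 1.0;
        double d1 = std::fabs(px[i + m] - py[j + m]);
        if (d1 > dm) dm = d1;
        if (dm <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Cross fuzzy membership means at dims m and m+1 (all ordered pairs).
// [[Rcpp::export(name = ".cross_fuzzy_phis_cpp")]]
NumericVector cross_fuzzy_phis_cpp(NumericVector x, NumericVector y,
                                   int m, double r, double nexp) {
  int n = x.size(), nt = n - m;
  const double* px = REAL(x);
  const double* py = REAL(y);
  std::vector<double> mx_m(nt), mx_m1(nt), my_m(nt), my_m1(nt);
  for (int i = 0; i < nt; ++i) {
    double sx = 0.0, sy = 0.0;
    for (int k = 0; k < m; ++k) { sx += px[i + k]; sy += py[i + k]; }
    mx_m[i] = sx / (double)m;         my_m[i] = sy / (double)m;
    mx_m1[i] = (sx + px[i + m]) / (double)(m + 1);
    my_m1[i] = (sy + py[i + m]) / (double)(m + 1);
  }
  double sm = 0.0, sm1 = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < nt; ++j) {
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double v = std::fabs((px[i + k] - mx_m[i]) - (py[j + k] - my_m[j]));
        if (v > dm) dm = v;
      }
      for (int k = 0; k <= m; ++k) {
        double v = std::fabs((px[i + k] - mx_m1[i]) - (py[j + k] - my_m1[j]));
        if (v > dm1) dm1 = v;
      }
      sm += std::exp(-std::pow(dm / r, nexp));
      sm1 += std::exp(-std::pow(dm1 / r, nexp));
    }
  }
  double npairs = (double)nt * (double)nt;
  return NumericVector::create(sm / npairs, sm1 / npairs);
}

// Cross correlation sums C_m and C_{m+1} for the K2-style estimator:
// fraction of ordered (x-template, y-template) pairs within r.
// [[Rcpp::export(name = ".cross_corr_sums_cpp")]]
NumericVector cross_corr_sums_cpp(NumericVector x, NumericVector y,
                                  int m, double r) {
  int n = x.size();
  const double* px = REAL(x);
  const double* py = REAL(y);
  double cm = 0.0, cm1 = 0.0;
  int nt = n - m + 1;
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < nt; ++j)
      if (cheb(px + i, py + j, m) <= r) cm += 1.0;
  int nt1 = n - m;
  for (int i = 0; i < nt1; ++i)
    for (int j = 0; j < nt1; ++j)
      if (cheb(px + i, py + j, m + 1) <= r) cm1 += 1.0;
  return NumericVector::create(cm / ((double)nt * (double)nt),
                               cm1 / ((double)nt1 * (double)nt1));
}

// Histogram of pairwise Chebyshev template distances (i<j), equal-width
// bins over [0, max distance]; used by distribution entropy.
// [[Rcpp::export(name = ".dist_hist_cpp")]]
NumericVector dist_hist_cpp(NumericVector x, int m, int nbins) {
  int n = x.size(), nt = n - m + 1;
  const double* p = REAL(x);
  double dmax = 0.0;
  for (int i = 0; i < nt; ++i)
    for (int j = i + 1; j < nt; ++j) {
      double d = cheb(p + i, p + j, m);
      if (d > dmax) dmax = d;
    }
  NumericVector counts(nbins);
  for (int i = 0; i < nt; ++i)
    for (int j = i + 1; j < nt; ++j) {
      double d = cheb(p + i, p + j, m);
      int b = (dmax > 0.0) ? (int)(d / dmax * nbins) : 0;
      if (b >= nbins) b = nbins - 1;
      counts[b] += 1.0;
    }
  return counts;
}

// Cross version of dist_hist over all ordered (x-template, y-template) pairs.
// [[Rcpp::export(name = ".cross_dist_hist_cpp")]]
NumericVector cross_dist_hist_cpp(NumericVector x, NumericVector y,
                                  int m, int nbins) {
  int n = x.size(), nt = n - m + 1;
  const double* px = REAL(x);
  const double* py = REAL(y);
  double dmax = 0.0;
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < nt; ++j) {
      double d = cheb(px + i, py + j, m);
      if (d > dmax) dmax = d;
    }
  NumericVector counts(nbins);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < nt; ++j) {
      double d = cheb(px + i, py + j, m);
      int b = (dmax > 0.0) ? (int)(d / dmax * nbins) : 0;
      if (b >= nbins) b = nbins - 1;
      counts[b] += 1.0;
    }
  return counts;
}

// Range-entropy pair counts: SampEn-style but with the normalized range
// distance ((max-min)/(max+min) of componentwise absolute differences).
// [[Rcpp::export(name = ".rangeen_counts_cpp")]]
NumericVector rangeen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size(), nt = n - m;
  const double* p = REAL(x);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double mx = 0.0, mn = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double v = std::fabs(p[i + k] - p[j + k]);
        if (v > mx) mx = v;
        if (v < mn) mn = v;
      }
      double dm = (mx + mn > 0.0) ? (mx - mn) / (mx + mn) : 0.0;
      if (dm <= r) {
        B += 1.0;
        double v = std::fabs(p[i + m] - p[j + m]);
        double mx1 = (v > mx) ? v : mx, mn1 = (v < mn) ? v : mn;
        double dm1 = (mx1 + mn1 > 0.0) ? (mx1 - mn1) / (mx1 + mn1) : 0.0;
        if (dm1 <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Bubble-sort swap count per embedded window of length m.
// [[Rcpp::export(name = ".bubble_swaps_cpp")]]
IntegerVector bubble_swaps_cpp(NumericVector x, int m) {
  int n = x.size(), nt = n - m + 1;
  const double* p = REAL(x);
  IntegerVector out(nt);
  std::vector<double> w(m);
  for (int i = 0; i < nt; ++i) {
    for (int k = 0; k < m; ++k) w[k] = p[i + k];
    int swaps = 0;
    for (int a = 0; a < m - 1; ++a)
      for (int b = 0; b < m - 1 - a; ++b)
        if (w[b] > w[b + 1]) { std::swap(w[b], w[b + 1]); ++swaps; }
    out[i] = swaps;
  }
  return out;
}

// Fraction of template pairs (i<j) whose angular distance
// acos(cosine similarity)/pi is at most tol. Zero-norm templates are
// treated as parallel to each other and orthogonal to non-zero ones.
// [[Rcpp::export(name = ".cosine_pair_frac_cpp")]]
double cosine_pair_frac_cpp(NumericVector x, int m, double tol) {
  int n = x.size(), nt = n - m + 1;
  const double* p = REAL(x);
  std::vector<double> nrm(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += p[i + k] * p[i + k];
    nrm[i] = std::sqrt(s);
  }
  double cnt = 0.0, tot = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      tot += 1.0;
      double sim;
      if (nrm[i] == 0.0 && nrm[j] == 0.0) sim = 1.0;
      else if (nrm[i] == 0.0 || nrm[j] == 0.0) sim = 0.0;
      else {
        double dot = 0.0;
        for (int k = 0; k < m; ++k) dot += p[i + k] * p[j + k];
        sim = dot / (nrm[i] * nrm[j]);
        if (sim > 1.0) sim = 1.0;
        if (sim < -1.0) sim = -1.0;
      }
      double ang = std::acos(sim) / M_PI;
      if (ang <= tol) cnt += 1.0;
    }
  }
  return cnt / tot;
}
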