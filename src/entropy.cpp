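#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Digamma values psi(1..n), cached because the averaged estimator touches
// every m = 1..n-1 for every genotype class inside permutation loops.
static const double *digamma_table(int n) {
  static std::vector<double> tab;
  if ((int)tab.size() <= n) {
    int old = (int)tab.size();
    if (old == 0) {
      tab.push_back(NA_REAL); // index 0 unused
      old = 1;
    }
    tab.resize(n + 1);
    for (int m = old; m <= n; ++m) tab[m] = R::digamma((double)m);
  }
  return tab.data();
}

struct StdLog {
  double operator()(double v) const { return std::log(v); }
};

// Branch-light polynomial log: reduce to m in [sqrt(1/2), sqrt(2)), then
// atanh series in t = (m-1)/(m+1), |t| <= 0.1716; absolute error ~1e-13.
// Only used inside permutation-null accumulation, where scores are compared
// at the 1e-2 scale; every user-facing estimate uses the libm log.
struct FastLog {
  double operator()(double x) const {
    std::uint64_t bits;
    std::memcpy(&bits, &x, 8);
    int e = (int)((bits >> 52) & 0x7FF);
    if (e == 0) return std::log(x); // subnormal: take the slow exact path
    e -= 1023;
    bits = (bits & 0x000FFFFFFFFFFFFFULL) | 0x3FF0000000000000ULL;
    double m;
    std::memcpy(&m, &bits, 8);
    const bool hi = m > 1.4142135623730951;
    m = hi ? m * 0.5 : m;
    e += hi ? 1 : 0;
    const double t = (m - 1.0) / (m + 1.0);
    const double t2 = t * t;
    const double p = 2.0 * t *
      (1.0 + t2 * (1.0 / 3 + t2 * (1.0 / 5 + t2 * (1.0 / 7 +
       t2 * (1.0 / 9 + t2 * (1.0 / 11 + t2 * (1.0 / 13)))))));
    return p + e * 0.6931471805599453;
  }
};

// Break exact ties in a sorted vector: the j-th member of each run of equal
// values gets an offset j * 1e-10 * range.  The result depends only on the
// multiset of values, so estimates are invariant to the input ordering.
// Returns false when the data remain degenerate (zero range, or equal
// neighbours that even the tie offsets could not separate).
static bool prepare_sorted(std::vector<double> &x) {
  const int n = (int)x.size();
  std::sort(x.begin(), x.end());
  const double range = x[n - 1] - x[0];
  if (!(range > 0.0)) return false;
  const double eps = 1e-10 * range;
  bool tied = false;
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && x[j] == x[i]) ++j;
    if (j > i + 1) {
      tied = true;
      for (int k = i + 1; k < j; ++k) x[k] += (k - i) * eps;
    }
    i = j;
  }
  if (tied) {
    std::sort(x.begin(), x.end()); // offsets may cross a tiny true gap
    for (int k = 1; k < n; ++k)
      if (!(x[k] > x[k - 1])) return false;
  }
  return true;
}

// H_{m,n} for one m: mean_k log((n/m) d_{k,m}) - psi(m) + log(m)
//                  = log(n) + mean_k log(d_{k,m}) - psi(m).
// x must be sorted and strictly increasing (prepare_sorted).
template <class LogF>
static double entropy_fixed_m_core(const std::vector<double> &x, int m,
                                   const double *psi, LogF lg) {
  const int n = (int)x.size();
  const int K = n - m;
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += lg(x[k + m] - x[k]);
  return std::log((double)n) + s / K - psi[m];
}

// <m>-averaged estimator: uniform mean of the fixed-m estimator over
// m = 1..n-1.  O(n^2) log evaluations.
template <class LogF>
static double entropy_avg_core(const std::vector<double> &x, LogF lg) {
  const int n = (int)x.size();
  const double *psi = digamma_table(n);
  double total = 0.0;
  for (int m = 1; m < n; ++m) total += entropy_fixed_m_core(x, m, psi, lg);
  return total / (n - 1);
}

// [[Rcpp::export]]
double entropy_fixed_m_cpp(NumericVector values, int m) {
  std::vector<double> x(values.begin(), values.end());
  if (!prepare_sorted(x)) return NA_REAL;
  return entropy_fixed_m_core(x, m, digamma_table((int)x.size()), StdLog());
}

// [[Rcpp::export]]
double entropy_avg_cpp(NumericVector values) {
  std::vector<double> x(values.begin(), values.end());
  if (!prepare_sorted(x)) return NA_REAL;
  return entropy_avg_core(x, StdLog());
}

// Weighted conditional entropy for one labelling g in 0..ncat-1:
// sum_g (n_g/n) * H_<m>(y | g), classes with n_g <= 1 contributing zero.
// `cls` is caller-provided scratch to avoid reallocation in hot loops.
template <class LogF>
static double cond_entropy_one(const std::vector<double> &y,
                               const int *g, int n, int ncat,
                               std::vector<std::vector<double> > &cls,
                               LogF lg) {
  for (int c = 0; c < ncat; ++c) cls[c].clear();
  for (int i = 0; i < n; ++i) cls[g[i]].push_back(y[i]);
  double h = 0.0;
  for (int c = 0; c < ncat; ++c) {
    const int ng = (int)cls[c].size();
    if (ng < 2) continue; // singleton/empty classes contribute zero
    if (!prepare_sorted(cls[c])) return NA_REAL; // irreparably tied class
    h += (double)ng / (double)n * entropy_avg_core(cls[c], lg);
  }
  return h;
}

// [[Rcpp::export]]
double cond_entropy_cpp(NumericVector y, IntegerVector g, int ncat) {
  const int n = y.size();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<std::vector<double> > cls(ncat);
  return cond_entropy_one(yv, INTEGER(g), n, ncat, cls, StdLog());
}

// Conditional entropy of the same phenotype under several labellings
// (columns of `labels`), e.g. every SNP combination of one order.
// [[Rcpp::export]]
NumericVector cond_entropy_multi_cpp(NumericVector y, IntegerMatrix labels,
                                     int ncat) {
  const int n = y.size();
  const int ncombo = labels.ncol();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<std::vector<double> > cls(ncat);
  NumericVector out(ncombo);
  for (int cb = 0; cb < ncombo; ++cb)
    out[cb] = cond_entropy_one(yv, &labels[(R_xlen_t)cb * n], n, ncat, cls,
                               StdLog());
  return out;
}

// Permutation null kernel: draws `nperm` phenotype permutations with R's
// RNG (Fisher-Yates via R_unif_index, so results are reproducible from
// set.seed) and for each computes max over label columns of
// IG = hp - H(P|G) on the permuted phenotype.  The marginal entropy hp is
// permutation-invariant and passed in precomputed.
//
// The phenotype multiset never changes across permutations, so y is sorted
// once and each permuted class is gathered already sorted by walking the
// global order (classes then need no per-permutation sort; tie offsets, if
// any, are applied per class on the rare tied path).
// [[Rcpp::export]]
NumericVector perm_max_ig_cpp(NumericVector y, IntegerMatrix labels, int ncat,
                              int nperm, double hp) {
  const int n = y.size();
  const int ncombo = labels.ncol();
  NumericVector out(nperm);

  // global ascending order of y: ord[j] = index of j-th smallest value
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return y[a] < y[b]; });

  std::vector<int> perm(n), inv(n);   // inv[sample slot of permuted value]
  std::vector<int> lab_sorted(n);     // labels along the global value order
  std::vector<std::vector<double> > cls(ncat);
  for (int c = 0; c < ncat; ++c) cls[c].reserve(n);
  const FastLog lg;
  RNGScope rng;

  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG stream
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)R_unif_index((double)(i + 1));
      std::swap(perm[i], perm[j]);
    }
    // sample i carries value y[perm[i]]; invert to map values -> samples
    for (int i = 0; i < n; ++i) inv[perm[i]] = i;
    double best = R_NegInf;
    for (int cb = 0; cb < ncombo; ++cb) {
      const int *lab = &labels[(R_xlen_t)cb * n];
      for (int j = 0; j < n; ++j) lab_sorted[j] = lab[inv[ord[j]]];
      for (int c = 0; c < ncat; ++c) cls[c].clear();
      for (int j = 0; j < n; ++j) cls[lab_sorted[j]].push_back(y[ord[j]]);
      double h = 0.0;
      for (int c = 0; c < ncat; ++c) {
        const int ng = (int)cls[c].size();
        if (ng < 2) continue;
        // gathered sorted; fall back to the tie policy only on duplicates
        bool strict = true;
        for (int k = 1; k < ng; ++k)
          if (!(cls[c][k] > cls[c][k - 1])) { strict = false; break; }
        if (!strict && !prepare_sorted(cls[c]))
          stop("degenerate (fully tied) phenotype class in a permuted dataset");
        h += (double)ng / (double)n * entropy_avg_core(cls[c], lg);
      }
      const double ig = hp - h;
      if (ig > best) best = ig;
    }
    out[p] = best;
  }
  return out;
}
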