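#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Circular binary segmentation internals.
//
// The circular two-sample statistic for an interval x[0..n-1] compares the
// mean of a contiguous window (arc) of length L against the mean of its
// complement, standardized by the interval's sample standard deviation:
//
//   T(a, L) = (mean(window) - mean(rest)) / (sigma * sqrt(1/L + 1/(n-L)))
//           = D / (sigma * sqrt(L * (n - L) / n)),
//
// where D is the centered window sum.  sigma is held fixed at the sample sd
// of the whole interval, so it is invariant under permutation and the
// permutation null distribution of max|T| depends on the data only through
// the multiset of values.

// Maximum circular statistic over all windows; returns the statistic and the
// 1-based inclusive bounds [a, b] of the best arc.
// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x) {
  const int n = x.size();
  if (n < 2) return List::create(_["stat"] = 0.0, _["a"] = 1, _["b"] = n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += x[i];
  const double mean = total / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
  const double sigma = std::sqrt(ss / (n - 1));
  if (sigma <= 1e-12 * (1.0 + std::fabs(mean)))
    return List::create(_["stat"] = 0.0, _["a"] = 1, _["b"] = n);

  // centered cumulative sums: C[i] = sum_{j<i} (x[j] - mean), C[0] = 0
  std::vector<double> C(n + 1);
  C[0] = 0.0;
  for (int i = 0; i < n; ++i) C[i + 1] = C[i] + (x[i] - mean);

  double best = -1.0;
  int best_a = 1, best_b = n;
  for (int L = 1; L <= n - 1; ++L) {
    const double denom = sigma * std::sqrt((double)L * (n - L) / n);
    // best window of this length
    double dmax = -1.0;
    int imax = 0;
    for (int i = 0; i + L <= n; ++i) {
      const double d = std::fabs(C[i + L] - C[i]);
      if (d > dmax) { dmax = d; imax = i; }
    }
    const double stat = dmax / denom;
    if (stat > best) {
      best = stat;
      best_a = imax + 1;        // window start, 1-based
      best_b = imax + L;        // window end, 1-based inclusive
    }
  }
  return List::create(_["stat"] = best, _["a"] = best_a, _["b"] = best_b);
}

// Permutation test for the max circular statistic.  Counts permutations whose
// max statistic reaches stat_obs.  Decision is exactly that of the full
// n_perm-permutation test:
//  * lengths L whose permutation-invariant bound (sum of the L largest
//    |x - mean|) cannot reach stat_obs are skipped for every permutation;
//  * per permutation, lengths whose range bound (max C - min C) cannot reach
//    stat_obs are skipped;
//  * sampling is curtailed once the exceedance count c reaches
//    ceil(alpha * n_perm): the final estimate c/n_perm would then be >= alpha
//    regardless of the remaining permutations, so the split is rejected.
// [[Rcpp::export(name = ".cbs_perm_test")]]
List cbs_perm_test(NumericVector x, double stat_obs, int n_perm, double alpha,
                   int seed) {
  const int n = x.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += x[i];
  const double mean = total / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
  const double sigma = std::sqrt(ss / (n - 1));
  if (sigma <= 1e-12 * (1.0 + std::fabs(mean)) || stat_obs <= 0.0)
    return List::create(_["p"] = 1.0, _["exceed"] = n_perm,
                        _["n_done"] = 0, _["significant"] = false);

  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) z[i] = x[i] - mean;

  // permutation-invariant bound per window length
  std::vector<double> absz(z.size());
  for (int i = 0; i < n; ++i) absz[i] = std::fabs(z[i]);
  std::sort(absz.begin(), absz.end(), std::greater<double>());
  // S[k] = sum of the k largest |z|; the centered sum of a window of length
  // L (equivalently of its complement, up to sign) is bounded by
  // S[min(L, n - L)]
  std::vector<double> S(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) S[k] = S[k - 1] + absz[k - 1];
  std::vector<int> cand;
  std::vector<double> thresh(n, 0.0);  // |D| needed at length L
  for (int L = 1; L <= n - 1; ++L) {
    const double denom = sigma * std::sqrt((double)L * (n - L) / n);
    thresh[L] = stat_obs * denom;
    if (S[std::min(L, n - L)] >= thresh[L]) cand.push_back(L);
  }

  const int stop_count = (int)std::ceil(alpha * n_perm);
  std::mt19937 rng((uint32_t)seed);
  std::vector<double> C(n + 1);
  int exceed = 0, done = 0;

  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle of centered values
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(z[i], z[u(rng)]);
    }
    C[0] = 0.0;
    double cmin = 0.0, cmax = 0.0;
    for (int i = 0; i < n; ++i) {
      C[i + 1] = C[i] + z[i];
      if (C[i + 1] < cmin) cmin = C[i + 1];
      if (C[i + 1] > cmax) cmax = C[i + 1];
    }
    const double rng_bound = cmax - cmin;  // bounds |D| for every window
    bool hit = false;
    for (size_t ci = 0; ci < cand.size() && !hit; ++ci) {
      const int L = cand[ci];
      const double th = thresh[L];
      if (rng_bound < th) continue;
      for (int i = 0; i + L <= n; ++i) {
        if (std::fabs(C[i + L] - C[i]) >= th) { hit = true; break; }
      }
    }
    ++done;
    if (hit) {
      ++exceed;
      if (exceed >= stop_count) break;  // p >= alpha is now certain
    }
  }
  const bool significant = exceed < stop_count &&
    ((double)exceed / n_perm) < alpha;
  return List::create(_["p"] = (double)exceed / n_perm,
                      _["exceed"] = exceed, _["n_done"] = done,
                      _["significant"] = significant);
}

// Scaled forward-backward for a homogeneous chain whose transition matrix is
// p_same on the diagonal and (1 - p_same)/(S - 1) elsewhere.  logem is the
// n x S matrix of log emission densities; init the initial distribution.
// Returns marginal state responsibilities and the data log-likelihood.
// [[Rcpp::export(name = ".hmm_fb")]]
List hmm_fb(NumericMatrix logem, NumericVector init, double p_same) {
  const int n = logem.nrow(), S = logem.ncol();
  const double p_diff = (1.0 - p_same) / (S - 1);
  NumericMatrix gamma(n, S);
  std::vector<double> alpha(n * S), beta(n * S), scale(n), mrow(n);
  double loglik = 0.0;

  // emissions rescaled per row to avoid underflow
  std::vector<double> em(n * S);
  for (int i = 0; i < n; ++i) {
    double m = logem(i, 0);
    for (int s = 1; s < S; ++s) if (logem(i, s) > m) m = logem(i, s);
    mrow[i] = m;
    for (int s = 0; s < S; ++s) em[i * S + s] = std::exp(logem(i, s) - m);
  }

  // forward
  double norm = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha[s] = init[s] * em[s];
    norm += alpha[s];
  }
  scale[0] = norm;
  for (int s = 0; s < S; ++s) alpha[s] /= norm;
  for (int i = 1; i < n; ++i) {
    double prev_sum = 0.0;
    for (int s = 0; s < S; ++s) prev_sum += alpha[(i - 1) * S + s];
    norm = 0.0;
    for (int s = 0; s < S; ++s) {
      const double trans = p_diff * prev_sum +
        (p_same - p_diff) * alpha[(i - 1) * S + s];
      alpha[i * S + s] = trans * em[i * S + s];
      norm += alpha[i * S + s];
    }
    scale[i] = norm;
    for (int s = 0; s < S; ++s) alpha[i * S + s] /= norm;
  }
  for (int i = 0; i < n; ++i) loglik += std::log(scale[i]) + mrow[i];

  // backward
  for (int s = 0; s < S; ++s) beta[(n - 1) * S + s] = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    double wsum = 0.0;
    for (int s = 0; s < S; ++s)
      wsum += em[(i + 1) * S + s] * beta[(i + 1) * S + s];
    for (int s = 0; s < S; ++s) {
      const double w = em[(i + 1) * S + s] * beta[(i + 1) * S + s];
      beta[i * S + s] = (p_diff * wsum + (p_same - p_diff) * w) / scale[i + 1];
    }
  }

  for (int i = 0; i < n; ++i) {
    double g = 0.0;
    for (int s = 0; s < S; ++s) {
      gamma(i, s) = alpha[i * S + s] * beta[i * S + s];
      g += gamma(i, s);
    }
    for (int s = 0; s < S; ++s) gamma(i, s) /= g;
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik);
}
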