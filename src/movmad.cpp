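#include <Rcpp.h>
#include <algorithm>
#include <cstdio>
#include <vector>

using namespace Rcpp;

// k-th smallest (1-based) absolute deviation |S[j] - m| over a sorted
// window S, via selection from the two sorted deviation sequences to the
// right (S[p..] - m) and to the left (m - S[p-1..0]) of m.
static double kth_dev(const std::vector<double> &S, double m, int k) {
  const int n = static_cast<int>(S.size());
  const int p = static_cast<int>(
      std::lower_bound(S.begin(), S.end(), m) - S.begin());
  int aLo = 0, bLo = 0;
  const int nA = n - p;   // deviations S[p + i] - m, ascending
  const int nB = p;       // deviations m - S[p - 1 - j], ascending
  while (true) {
    if (aLo == nA) return m - S[p - 1 - (bLo + k - 1)];
    if (bLo == nB) return S[p + aLo + k - 1] - m;
    double a0 = S[p + aLo] - m, b0 = m - S[p - 1 - bLo];
    if (k == 1) return a0 < b0 ? a0 : b0;
    int ia = std::min(nA - aLo, k / 2);
    int ib = std::min(nB - bLo, k - k / 2);
    double av = S[p + aLo + ia - 1] - m;
    double bv = m - S[p - 1 - (bLo + ib - 1)];
    if (av < bv) {
      aLo += ia;
      k -= ia;
    } else {
      bLo += ib;
      k -= ib;
    }
  }
}

static double window_mad(const std::vector<double> &S) {
  const int n = static_cast<int>(S.size());
  double m = (n % 2 == 1) ? S[n / 2] : 0.5 * (S[n / 2 - 1] + S[n / 2]);
  if (n % 2 == 1) return kth_dev(S, m, (n + 1) / 2);
  return 0.5 * (kth_dev(S, m, n / 2) + kth_dev(S, m, n / 2 + 1));
}

// Moving median absolute deviation with a centred window that shrinks at
// the edges. For 1-based index i the window covers
// [i - floor(w/2), i + ceil(w/2) - 1] intersected with [1, n] (an even
// window extends one sample further to the left of the centre). Medians
// of even counts average the two middle order statistics, matching
// stats::median().
// [[Rcpp::export]]
NumericVector movmad_cpp(NumericVector x, int window) {
  const int n = x.size();
  if (window < 1) stop("`window` must be a positive integer");
  NumericVector out(n);
  const int left = window / 2;
  const int right = (window + 1) / 2 - 1;
  std::vector<double> S;
  S.reserve(std::min(n, window) + 1);
  // initial window for i = 0: x[0 .. right]
  for (int j = 0; j <= std::min(n - 1, right); ++j) S.push_back(x[j]);
  std::sort(S.begin(), S.end());
  for (int i = 0; i < n; ++i) {
    out[i] = window_mad(S);
    if (i == n - 1) break;
    // advance window to centre i + 1: drop x[i - left], add x[i + 1 + right]
    int drop = i - left;
    if (drop >= 0) {
      auto it = std::lower_bound(S.begin(), S.end(), x[drop]);
      S.erase(it);
    }
    int add = i + 1 + right;
    if (add < n) {
      auto it = std::upper_bound(S.begin(), S.end(), x[add]);
      S.insert(it, x[add]);
    }
  }
  return out;
}

// FNV-1a 64-bit hash over a raw vector; used for data-manifest fingerprints.
// [[Rcpp::export]]
std::string fnv1a_cpp(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= static_cast<uint64_t>(bytes[i]);
    h *= 1099511628211ULL;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx",
                static_cast<unsigned long long>(h));
  return std::string(buf);
}
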