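#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history phrase count, Kaspar-Schuster scheme.
// Symbols are arbitrary non-negative integers; only equality is used.
// [[Rcpp::export(name = ".lzc_raw_cpp")]]
int lzc_raw_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty symbol sequence");
  int c = 1;       // phrase count; first symbol is always a phrase
  int l = 1;       // length of prefix already parsed
  int i = 0;       // candidate copy-source offset within the prefix
  int k = 1;       // current match extension length
  int k_max = 1;   // longest match over sources tried for this phrase
  if (n == 1) return 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      k++;
      if (l + k > n) { c++; break; }
    } else {
      if (k > k_max) k_max = k;
      i++;
      if (i == l) {         // all sources exhausted: phrase complete
        c++;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Sample entropy template-match counts (Richman & Moorman convention):
// B = pairs of m-length templates within Chebyshev distance r,
// A = pairs of (m+1)-length templates within r, both over the N-m template
// start points, self-matches excluded.  r is absolute here.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  if (m < 1) stop("m must be >= 1");
  if (N < m + 2) stop("epoch too short for embedding dimension m");
  const int nt = N - m;  // number of template start points
  double A = 0.0, B = 0.0;
  // Sort template start points by first coordinate: a pair can only match
  // if its first coordinates are within r, so each i is compared against a
  // contiguous window of the sorted order.  Every unordered pair is seen
  // exactly once.  Falls back to O(nt^2) only when everything matches.
  std::vector<int> ord(nt);
  for (int i = 0; i < nt; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  for (int a = 0; a < nt - 1; a++) {
    const int i = ord[a];
    const double xi = x[i];
    for (int b = a + 1; b < nt && x[ord[b]] - xi <= r; b++) {
      const int j = ord[b];
      bool ok = true;
      for (int k = 1; k < m; k++) {
        if (std::abs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
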