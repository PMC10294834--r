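#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Count inversions in v by merge sort; v is permuted to sorted order.
static double merge_count(std::vector<double> &v, std::vector<double> &buf,
                          size_t lo, size_t hi) {
  if (hi - lo < 2) return 0.0;
  size_t mid = lo + (hi - lo) / 2;
  double inv = merge_count(v, buf, lo, mid) + merge_count(v, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (v[j] < v[i]) {           // strict: ties are not inversions
      inv += (double)(mid - i);
      buf[k++] = v[j++];
    } else {
      buf[k++] = v[i++];
    }
  }
  while (i < mid) buf[k++] = v[i++];
  while (j < hi) buf[k++] = v[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, v.begin() + lo);
  return inv;
}

// Kendall's tau-b via Knight's O(n log n) algorithm: sort by (x, y), count
// tie corrections, count discordant pairs as inversions of the y sequence.
// [[Rcpp::export(name = ".kendall_tau_cpp")]]
double kendall_tau_cpp(NumericVector x, NumericVector y) {
  size_t n = x.size();
  if (n < 2 || (size_t)y.size() != n) return NA_REAL;
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> ys(n);
  for (size_t i = 0; i < n; ++i) ys[i] = y[ord[i]];

  double n0 = (double)n * (n - 1) / 2.0;
  double n1 = 0.0, n3 = 0.0;   // ties in x; ties in both
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && x[ord[j]] == x[ord[i]]) ++j;
    double t = (double)(j - i);
    n1 += t * (t - 1) / 2.0;
    size_t a = i;
    while (a < j) {
      size_t b = a;
      while (b < j && ys[b] == ys[a]) ++b;
      double u = (double)(b - a);
      n3 += u * (u - 1) / 2.0;
      a = b;
    }
    i = j;
  }
  double n2 = 0.0;             // ties in y overall
  std::vector<double> ysorted(ys);
  std::sort(ysorted.begin(), ysorted.end());
  i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && ysorted[j] == ysorted[i]) ++j;
    double t = (double)(j - i);
    n2 += t * (t - 1) / 2.0;
    i = j;
  }

  std::vector<double> buf(n);
  double swaps = merge_count(ys, buf, 0, n);
  double num = n0 - n1 - n2 + n3 - 2.0 * swaps;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den == 0.0) return NA_REAL;
  return num / den;
}
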