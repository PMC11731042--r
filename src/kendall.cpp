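#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Count strict inversions (pairs i<j with a[i] > a[j]) by mergesort; sorts a.
static long long merge_count(std::vector<double>& a, std::vector<double>& tmp,
                             int lo, int hi) {
  if (hi - lo < 2) return 0;
  int mid = (lo + hi) / 2;
  long long cnt = merge_count(a, tmp, lo, mid) + merge_count(a, tmp, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (a[j] < a[i]) { cnt += mid - i; tmp[k++] = a[j++]; }
    else tmp[k++] = a[i++];
  }
  while (i < mid) tmp[k++] = a[i++];
  while (j < hi) tmp[k++] = a[j++];
  for (int t = lo; t < hi; ++t) a[t] = tmp[t];
  return cnt;
}

// Sum of t*(t-1)/2 over runs of equal values in a sorted vector.
static double tie_pairs(const std::vector<double>& sorted) {
  double out = 0;
  long long run = 1;
  for (size_t i = 1; i < sorted.size(); ++i) {
    if (sorted[i] == sorted[i - 1]) ++run;
    else { out += (double)run * (run - 1) / 2.0; run = 1; }
  }
  out += (double)run * (run - 1) / 2.0;
  return out;
}

// Exact tie-corrected Kendall tau-b via Knight's O(n log n) algorithm.
// [[Rcpp::export]]
double kendall_tau_b(NumericVector x, NumericVector y) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n < 2) return NA_REAL;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = y[idx[i]];
  // n1: tie pairs in x; n3: tie pairs in (x, y) jointly
  double n1 = 0, n3 = 0;
  {
    long long runx = 1, runxy = 1;
    for (int i = 1; i < n; ++i) {
      bool tx = x[idx[i]] == x[idx[i - 1]];
      bool txy = tx && (y[idx[i]] == y[idx[i - 1]]);
      if (tx) ++runx; else { n1 += (double)runx * (runx - 1) / 2.0; runx = 1; }
      if (txy) ++runxy; else { n3 += (double)runxy * (runxy - 1) / 2.0; runxy = 1; }
    }
    n1 += (double)runx * (runx - 1) / 2.0;
    n3 += (double)runxy * (runxy - 1) / 2.0;
  }
  std::vector<double> ysort(y.begin(), y.end());
  std::sort(ysort.begin(), ysort.end());
  double n2 = tie_pairs(ysort);
  std::vector<double> tmp(n);
  long long s = merge_count(ys, tmp, 0, n);
  double n0 = (double)n * (n - 1) / 2.0;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den <= 0) return 0.0;
  return (n0 - n1 - n2 + n3 - 2.0 * (double)s) / den;
}

// Kendall tau-b of y against many reference templates, using precomputed
// per-template sort orders (ord, 0-based, ascending template value), tie-group
// ids per sorted position (grp) and template tie-pair counts (n1).
// [[Rcpp::export]]
NumericVector kendall_tau_templates(NumericVector y, IntegerMatrix ord,
                                    IntegerMatrix grp, NumericVector n1) {
  int n = y.size();
  int n_ref = ord.ncol();
  if (ord.nrow() != n || grp.nrow() != n || n1.size() != n_ref)
    stop("reference set does not match series length");
  std::vector<double> ysort(y.begin(), y.end());
  std::sort(ysort.begin(), ysort.end());
  double n2 = tie_pairs(ysort);
  double n0 = (double)n * (n - 1) / 2.0;
  NumericVector out(n_ref);
  std::vector<double> y2(n), tmp(n);
  for (int k = 0; k < n_ref; ++k) {
    for (int i = 0; i < n; ++i) y2[i] = y[ord(i, k)];
    // sort y within template tie groups; joint ties contribute n3
    double n3 = 0;
    int i = 0;
    while (i < n) {
      int j = i + 1;
      while (j < n && grp(j, k) == grp(i, k)) ++j;
      if (j - i > 1) {
        std::sort(y2.begin() + i, y2.begin() + j);
        long long run = 1;
        for (int t = i + 1; t < j; ++t) {
          if (y2[t] == y2[t - 1]) ++run;
          else { n3 += (double)run * (run - 1) / 2.0; run = 1; }
        }
        n3 += (double)run * (run - 1) / 2.0;
      }
      i = j;
    }
    long long s = merge_count(y2, tmp, 0, n);
    double den = std::sqrt((n0 - n1[k]) * (n0 - n2));
    out[k] = den <= 0 ? 0.0 : (n0 - n1[k] - n2 + n3 - 2.0 * (double)s) / den;
  }
  return out;
}
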