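#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Shannon entropy (bits) of a count vector.
static double count_entropy(const std::vector<int>& cnt, int total) {
  if (total <= 0) return 0.0;
  double e = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    if (cnt[c] > 0) {
      double p = (double)cnt[c] / (double)total;
      e -= p * std::log2(p);
    }
  }
  return e;
}

static int classes_present(const std::vector<int>& cnt) {
  int k = 0;
  for (size_t c = 0; c < cnt.size(); ++c) if (cnt[c] > 0) ++k;
  return k;
}

// Recursive Fayyad-Irani search over the sorted segment [lo, hi].
// xs: sorted values, ys: class codes (0-based) in the same order.
static void mdl_segment(const std::vector<double>& xs, const std::vector<int>& ys,
                        int lo, int hi, int nclass, std::vector<double>& cuts) {
  int n = hi - lo + 1;
  if (n < 2) return;

  std::vector<int> total_cnt(nclass, 0);
  for (int i = lo; i <= hi; ++i) total_cnt[ys[i]]++;
  double ent_s = count_entropy(total_cnt, n);
  int k = classes_present(total_cnt);
  if (k < 2) return;  // pure segment: nothing to gain

  // scan all boundaries between distinct adjacent values
  std::vector<int> left_cnt(nclass, 0);
  double best_w = R_PosInf;
  int best_i = -1;
  std::vector<int> best_left;
  for (int i = lo; i < hi; ++i) {
    left_cnt[ys[i]]++;
    if (xs[i] >= xs[i + 1]) continue;  // not a value boundary
    int n1 = i - lo + 1, n2 = n - n1;
    double e1 = count_entropy(left_cnt, n1);
    // right counts = total - left
    double e2;
    {
      std::vector<int> right_cnt(nclass);
      for (int c = 0; c < nclass; ++c) right_cnt[c] = total_cnt[c] - left_cnt[c];
      e2 = count_entropy(right_cnt, n2);
    }
    double w = ((double)n1 * e1 + (double)n2 * e2) / (double)n;
    if (w < best_w) {
      best_w = w;
      best_i = i;
      best_left = left_cnt;
    }
  }
  if (best_i < 0) return;  // constant segment

  // MDL acceptance criterion
  int n1 = best_i - lo + 1, n2 = n - n1;
  double e1 = count_entropy(best_left, n1);
  std::vector<int> right_cnt(nclass);
  for (int c = 0; c < nclass; ++c) right_cnt[c] = total_cnt[c] - best_left[c];
  double e2 = count_entropy(right_cnt, n2);
  int k1 = classes_present(best_left);
  int k2 = classes_present(right_cnt);
  double gain = ent_s - best_w;
  double delta = std::log2(std::pow(3.0, k) - 2.0) - (k * ent_s - k1 * e1 - k2 * e2);
  double thresh = (std::log2((double)n - 1.0) + delta) / (double)n;
  if (gain <= thresh) return;

  cuts.push_back((xs[best_i] + xs[best_i + 1]) / 2.0);
  mdl_segment(xs, ys, lo, best_i, nclass, cuts);
  mdl_segment(xs, ys, best_i + 1, hi, nclass, cuts);
}

// [[Rcpp::export(name = ".mdl_cut_points")]]
NumericVector mdl_cut_points(NumericVector x, IntegerVector y, int nclass) {
  int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> xs(n);
  std::vector<int> ys(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    ys[i] = y[ord[i]] - 1;  // to 0-based
    if (ys[i] < 0 || ys[i] >= nclass) stop("class code out of range");
  }
  std::vector<double> cuts;
  mdl_segment(xs, ys, 0, n - 1, nclass, cuts);
  std::sort(cuts.begin(), cuts.end());
  return wrap(cuts);
}
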