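#include <Rcpp.h>
using namespace Rcpp;

// SNIP baseline: iterative peak clipping with a decreasing window.
// y[i] <- min(y[i], (y[i-m] + y[i+m]) / 2) for m = iterations .. 1.
// The decreasing schedule avoids the stepped artefacts of the increasing
// variant on narrow MALDI peaks.
// [[Rcpp::export]]
NumericVector snip_baseline_cpp(NumericVector y, int iterations) {
  int n = y.size();
  NumericVector out = clone(y);
  if (n == 0 || iterations < 1) return out;
  std::vector<double> a(out.begin(), out.end());
  std::vector<double> b(a);
  double *cur = a.data(), *nxt = b.data();
  for (int m = iterations; m >= 1; --m) {
    if (2 * m >= n) continue;
    for (int i = 0; i < m; ++i) { nxt[i] = cur[i]; nxt[n - 1 - i] = cur[n - 1 - i]; }
    for (int i = m; i < n - m; ++i) {
      double avg = 0.5 * (cur[i - m] + cur[i + m]);
      nxt[i] = avg < cur[i] ? avg : cur[i];
    }
    std::swap(cur, nxt);
  }
  std::copy(cur, cur + n, out.begin());
  return out;
}

// Indices (1-based) of strict local maxima within +/- half_window points.
// Plateaus keep their left-most point.
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector y, int half_window) {
  int n = y.size();
  std::vector<int> out;
  for (int i = 0; i < n; ++i) {
    double yi = y[i];
    if (yi <= 0) continue;
    bool is_max = true;
    int lo = i - half_window < 0 ? 0 : i - half_window;
    int hi = i + half_window >= n ? n - 1 : i + half_window;
    for (int j = lo; j <= hi; ++j) {
      if (j == i) continue;
      if (y[j] > yi || (y[j] == yi && j < i)) { is_max = false; break; }
    }
    if (is_max) out.push_back(i + 1);
  }
  return wrap(out);
}
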