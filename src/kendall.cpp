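#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

// Kendall tau-a in O(n log n): sort by (x, y), count discordant pairs as
// strict inversions of y by iterative merge sort, and keep every tied pair
// in the denominator (tau-a, not tau-b).

static double merge_count_inversions(std::vector<double>& y) {
  const std::size_t n = y.size();
  std::vector<double> buf(n);
  double inv = 0.0;
  for (std::size_t width = 1; width < n; width *= 2) {
    for (std::size_t lo = 0; lo < n; lo += 2 * width) {
      const std::size_t mid = std::min(lo + width, n);
      const std::size_t hi = std::min(lo + 2 * width, n);
      if (mid >= hi) continue;
      std::size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (y[j] < y[i]) {          // strict: ties are not inversions
          inv += static_cast<double>(mid - i);
          buf[k++] = y[j++];
        } else {
          buf[k++] = y[i++];
        }
      }
      while (i < mid) buf[k++] = y[i++];
      while (j < hi) buf[k++] = y[j++];
      std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
    }
  }
  return inv;
}

static double tied_pairs(const std::vector<double>& v) {
  double t = 0.0;
  std::size_t run = 1;
  for (std::size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) {
      ++run;
    } else {
      t += 0.5 * run * (run - 1.0);
      run = 1;
    }
  }
  t += 0.5 * run * (run - 1.0);
  return t;
}

// [[Rcpp::export]]
double kendall_tau_a_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  const std::size_t n = x.size();
  std::vector<std::size_t> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](std::size_t a, std::size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  const double n0 = 0.5 * static_cast<double>(n) * (n - 1.0);

  double tx = 0.0, txy = 0.0;
  std::size_t run_x = 1, run_xy = 1;
  for (std::size_t i = 1; i < n; ++i) {
    const bool same_x = x[ord[i]] == x[ord[i - 1]];
    const bool same_xy = same_x && y[ord[i]] == y[ord[i - 1]];
    if (same_x) ++run_x; else { tx += 0.5 * run_x * (run_x - 1.0); run_x = 1; }
    if (same_xy) ++run_xy; else { txy += 0.5 * run_xy * (run_xy - 1.0); run_xy = 1; }
  }
  tx += 0.5 * run_x * (run_x - 1.0);
  txy += 0.5 * run_xy * (run_xy - 1.0);

  std::vector<double> ys(n);
  for (std::size_t i = 0; i < n; ++i) ys[i] = y[ord[i]];
  const double discordant = merge_count_inversions(ys);
  // ys is now sorted; reuse it for the y tie count
  const double ty = tied_pairs(ys);

  const double numerator = n0 - 2.0 * discordant - (tx + ty - txy);
  return numerator / n0;
}
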