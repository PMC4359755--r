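#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Reflect an out-of-range index without repeating the edge pixel
// (numpy "reflect" / scipy "mirror"): -1 -> 1, n -> n-2.
// Valid for |overhang| <= n-1, which window <= min(h, w) guarantees.
static inline int reflect_idx(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// Exact 2D median filter with reflect padding.  The image is rank
// transformed once (any consistent tie order preserves the median value),
// then a two-level count histogram over ranks slides along each output
// row: O(1) insert/remove per pixel entering/leaving the window and an
// O(sqrt(n)) order-statistic query per output pixel.  Exact for arbitrary
// doubles, unlike quantizing histogram filters.
// [[Rcpp::export]]
NumericMatrix median_filter_reflect(NumericMatrix x, int window) {
  const int h = x.nrow(), w = x.ncol();
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  if (window > h || window > w)
    stop("window exceeds image dimensions");
  NumericMatrix out(h, w);
  if (window == 1) {
    std::copy(x.begin(), x.end(), out.begin());
    return out;
  }
  const int p = (window - 1) / 2;
  const int n = h * w;

  // rank transform
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<int> rank(n);
  std::vector<double> sorted_vals(n);
  for (int r = 0; r < n; ++r) {
    rank[order[r]] = r;
    sorted_vals[r] = x[order[r]];
  }

  // two-level histogram over ranks
  int bucket = 1;
  while (bucket * bucket < n) bucket <<= 1;  // bucket width ~ sqrt(n)
  const int n_buckets = (n + bucket - 1) / bucket;
  std::vector<int> fine(n, 0), coarse(n_buckets, 0);
  auto add = [&](int rk) { ++fine[rk]; ++coarse[rk / bucket]; };
  auto rem = [&](int rk) { --fine[rk]; --coarse[rk / bucket]; };
  auto kth = [&](int k) {
    int b = 0;
    while (coarse[b] <= k) k -= coarse[b++];
    int rk = b * bucket;
    while (fine[rk] <= k) k -= fine[rk++];
    return sorted_vals[rk];
  };

  const int mid = (window * window) / 2;  // 0-based middle, window^2 odd
  std::vector<int> rr(window);
  for (int r = 0; r < h; ++r) {
    for (int k = 0; k < window; ++k) rr[k] = reflect_idx(r - p + k, h);
    std::fill(fine.begin(), fine.end(), 0);
    std::fill(coarse.begin(), coarse.end(), 0);
    for (int c = -p; c <= p; ++c) {
      int cc = reflect_idx(c, w);
      for (int k = 0; k < window; ++k) add(rank[cc * h + rr[k]]);
    }
    out(r, 0) = kth(mid);
    for (int c = 1; c < w; ++c) {
      int c_out = reflect_idx(c - 1 - p, w);
      int c_in = reflect_idx(c + p, w);
      for (int k = 0; k < window; ++k) {
        rem(rank[c_out * h + rr[k]]);
        add(rank[c_in * h + rr[k]]);
      }
      out(r, c) = kth(mid);
    }
  }
  return out;
}

// 8-connected component labelling of a binary mask (iterative flood fill).
// Labels are 1..n in scan order of each component's first pixel; background 0.
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        int pr = stack.back().first, pc = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  return lab;
}
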