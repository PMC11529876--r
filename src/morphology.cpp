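// Flat grayscale erosion/dilation with a disk structuring element,
// decomposed into horizontal chords: the disk is the union of rows
// [-w(dy), w(dy)] at vertical offsets dy, so erosion = min over dy of a
// 1-D running min of half-width w(dy) applied to the shifted row.  The
// running min uses the van Herk/Gil-Werman scheme, giving O(N * radius)
// total instead of O(N * radius^2).  The element is clipped at borders.
#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static void running_extreme_row(const double* in, double* out, int n,
                                int w, bool is_min) {
  // window [i-w, i+w] clipped to [0, n)
  if (w <= 0) { std::copy(in, in + n, out); return; }
  int k = 2 * w + 1;
  std::vector<double> pre(n), suf(n);
  for (int i = 0; i < n; ++i) {
    double v = in[i];
    if (i % k != 0) {
      double p = pre[i - 1];
      v = is_min ? std::min(v, p) : std::max(v, p);
    }
    pre[i] = v;
  }
  for (int i = n - 1; i >= 0; --i) {
    double v = in[i];
    if (i != n - 1 && (i + 1) % k != 0) {
      double s = suf[i + 1];
      v = is_min ? std::min(v, s) : std::max(v, s);
    }
    suf[i] = v;
  }
  for (int i = 0; i < n; ++i) {
    int lo = i - w, hi = i + w;
    if (hi > n - 1) hi = n - 1;
    if (lo < 0) lo = 0;
    // window [lo, hi] spans at most two blocks of size k
    double v;
    if (hi / k == lo / k) {
      // within one block: suf[lo] covers [lo, block_end], pre[hi] covers
      // [block_start, hi]; their combination over-covers but both bounded
      // by block; use direct pre/suf trick
      v = is_min ? std::min(suf[lo], pre[hi]) : std::max(suf[lo], pre[hi]);
      // when lo..hi inside one block, min(suf[lo], pre[hi]) still equals
      // min over [lo, hi] only if the block is fully covered; fall back:
      if (hi - lo + 1 < k && (lo % k != 0 || hi % k != k - 1)) {
        v = in[lo];
        for (int j = lo + 1; j <= hi; ++j)
          v = is_min ? std::min(v, in[j]) : std::max(v, in[j]);
      }
    } else {
      v = is_min ? std::min(suf[lo], pre[hi]) : std::max(suf[lo], pre[hi]);
    }
    out[i] = v;
  }
}

static NumericMatrix disk_filter(const NumericMatrix& img, int radius,
                                 bool is_min) {
  int h = img.nrow(), w = img.ncol();
  // chord half-widths per vertical offset
  std::vector<int> cw(2 * radius + 1);
  for (int dy = -radius; dy <= radius; ++dy)
    cw[dy + radius] = (int) std::floor(std::sqrt(
        (double) radius * radius - (double) dy * dy) + 1e-9);
  // horizontal pass per row for each distinct half-width
  std::vector<int> widths(cw);
  std::sort(widths.begin(), widths.end());
  widths.erase(std::unique(widths.begin(), widths.end()), widths.end());
  // store horizontal results keyed by width index
  std::map<int, std::vector<double> > hpass;
  std::vector<double> rowin(w), rowout(w);
  for (size_t k = 0; k < widths.size(); ++k) {
    std::vector<double> plane((size_t) h * w);
    for (int y = 0; y < h; ++y) {
      for (int x = 0; x < w; ++x) rowin[x] = img(y, x);
      running_extreme_row(rowin.data(), rowout.data(), w, widths[k], is_min);
      for (int x = 0; x < w; ++x) plane[(size_t) y * w + x] = rowout[x];
    }
    hpass[widths[k]] = plane;
  }
  NumericMatrix out(h, w);
  double init = is_min ? std::numeric_limits<double>::infinity()
                       : -std::numeric_limits<double>::infinity();
  std::fill(out.begin(), out.end(), init);
  for (int dy = -radius; dy <= radius; ++dy) {
    const std::vector<double>& plane = hpass[cw[dy + radius]];
    for (int y = 0; y < h; ++y) {
      int ys = y + dy;
      if (ys < 0 || ys >= h) continue;
      for (int x = 0; x < w; ++x) {
        double v = plane[(size_t) ys * w + x];
        double& o = out(y, x);
        o = is_min ? std::min(o, v) : std::max(o, v);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix disk_erode(NumericMatrix img, int radius) {
  return disk_filter(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix disk_dilate(NumericMatrix img, int radius) {
  return disk_filter(img, radius, false);
}
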