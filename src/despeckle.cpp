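#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Windowed non-local means with variance-subtracted weights: each pixel is
// replaced by a weighted average of pixels in a local search window, the
// weight decaying with the noise-corrected mean squared patch distance
// exp(-max(d2 - 2*sigma^2, 0) / h^2). img is expected in a domain where the
// noise is (approximately) additive and stationary with std sigma; the R
// wrapper log-transforms speckled images before calling this.
// [[Rcpp::export(name = ".nlm_filter")]]
NumericMatrix nlm_filter(NumericMatrix img, int patch, int search,
                         double h, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  int pr = patch / 2, sr = search / 2;
  double npatch = (2 * pr + 1) * (2 * pr + 1);
  double h2 = h * h;
  if (h2 <= 0) h2 = 1e-12;
  double noise2 = 2.0 * sigma * sigma;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double wsum = 0.0, acc = 0.0;
      for (int dc = -sr; dc <= sr; ++dc) {
        int c2 = c + dc;
        if (c2 < 0 || c2 >= nc) continue;
        for (int dr = -sr; dr <= sr; ++dr) {
          int r2 = r + dr;
          if (r2 < 0 || r2 >= nr) continue;
          double d2 = 0.0;
          for (int pc = -pr; pc <= pr; ++pc) {
            for (int pp = -pr; pp <= pr; ++pp) {
              int ra = std::min(std::max(r + pp, 0), nr - 1);
              int ca = std::min(std::max(c + pc, 0), nc - 1);
              int rb = std::min(std::max(r2 + pp, 0), nr - 1);
              int cb = std::min(std::max(c2 + pc, 0), nc - 1);
              double diff = img(ra, ca) - img(rb, cb);
              d2 += diff * diff;
            }
          }
          d2 = d2 / npatch - noise2;
          if (d2 < 0) d2 = 0;
          double w = std::exp(-d2 / h2);
          wsum += w;
          acc += w * img(r2, c2);
        }
      }
      out(r, c) = acc / wsum;
    }
  }
  return out;
}

// Square-window median filter with edge replication.
// [[Rcpp::export(name = ".median_filter")]]
NumericMatrix median_filter(NumericMatrix img, int window) {
  int nr = img.nrow(), nc = img.ncol();
  int half = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(window * window);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      for (int dc = -half; dc <= half; ++dc) {
        int c2 = std::min(std::max(c + dc, 0), nc - 1);
        for (int dr = -half; dr <= half; ++dr) {
          int r2 = std::min(std::max(r + dr, 0), nr - 1);
          buf.push_back(img(r2, c2));
        }
      }
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (buf.size() % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lo) / 2.0;
      }
      out(r, c) = med;
    }
  }
  return out;
}
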