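#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// R type-7 quantiles at two percentiles (lo < hi) from one buffer using
// nested nth_element passes: the hi statistic first, then the lo statistic
// inside the left partition.
static void quantile7_pair(std::vector<double> &buf, double lo_pct,
                           double hi_pct, double &qlo, double &qhi) {
  const R_xlen_t n = (R_xlen_t)buf.size();
  if (n == 1) { qlo = qhi = buf[0]; return; }
  double h_hi = (n - 1) * hi_pct / 100.0, h_lo = (n - 1) * lo_pct / 100.0;
  R_xlen_t k2 = (R_xlen_t)std::floor(h_hi), k1 = (R_xlen_t)std::floor(h_lo);
  double w2 = h_hi - k2, w1 = h_lo - k1;
  std::nth_element(buf.begin(), buf.begin() + k2, buf.end());
  qhi = buf[k2];
  if (w2 > 0)
    qhi += w2 * (*std::min_element(buf.begin() + k2 + 1, buf.end()) - qhi);
  if (k1 == k2) {
    qlo = buf[k1];
    if (w1 > 0)
      qlo += w1 * (*std::min_element(buf.begin() + k1 + 1, buf.end()) - qlo);
    return;
  }
  std::nth_element(buf.begin(), buf.begin() + k1, buf.begin() + k2);
  qlo = buf[k1];
  if (w1 > 0)  // next order stat lies in (k1, k2] (right of k2 is >= buf[k2])
    qlo += w1 * (*std::min_element(buf.begin() + k1 + 1, buf.begin() + k2 + 1) - qlo);
}

static void stretch_one(const double *src, int *dst, R_xlen_t n,
                        double lo_pct, double hi_pct,
                        std::vector<double> &buf) {
  buf.assign(src, src + n);
  double lo, hi;
  quantile7_pair(buf, lo_pct, hi_pct, lo, hi);
  if (hi <= lo) { std::fill(dst, dst + n, 0); return; }
  double sc = 255.0 / (hi - lo);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = (src[i] - lo) * sc;
    if (v < 0) v = 0; else if (v > 255) v = 255;
    dst[i] = (int)std::lround(v);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_stretch_frame(NumericMatrix frame, double lo_pct, double hi_pct) {
  IntegerMatrix out(frame.nrow(), frame.ncol());
  std::vector<double> buf;
  stretch_one(frame.begin(), out.begin(), frame.size(), lo_pct, hi_pct, buf);
  return out;
}

// Per-frame contrast stretch of a (rows, cols, frames) stack to 8-bit.
// [[Rcpp::export]]
IntegerVector cpp_stretch_video(NumericVector video, double lo_pct, double hi_pct) {
  IntegerVector dims = video.attr("dim");
  const R_xlen_t fsz = (R_xlen_t)dims[0] * dims[1];
  const int nf = dims[2];
  IntegerVector out(video.size());
  out.attr("dim") = dims;
  std::vector<double> buf;
  for (int t = 0; t < nf; ++t)
    stretch_one(REAL(video) + t * fsz, INTEGER(out) + t * fsz, fsz,
                lo_pct, hi_pct, buf);
  return out;
}
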