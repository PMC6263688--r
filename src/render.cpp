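#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian draws for full-frame sensor noise via the Marsaglia-Tsang
// ziggurat (128 layers) driven by R's uniform stream — R's inversion-based
// norm_rand is an order of magnitude slower at the tens of millions of
// draws a scene needs. Layer index and position reuse one uniform (the
// position keeps ~25 bits, ample for rendering noise). Deterministic for a
// given seed.
static double zx[129], zf[129];
static bool zinit = false;
static void zigg_setup() {
  const double r = 3.442619855899, v = 9.91256303526217e-3;
  zx[0] = v * std::exp(0.5 * r * r);  // base-layer extent
  zx[1] = r;
  for (int i = 2; i < 128; ++i)
    zx[i] = std::sqrt(-2.0 * std::log(v / zx[i - 1] +
                                      std::exp(-0.5 * zx[i - 1] * zx[i - 1])));
  zx[128] = 0.0;
  for (int i = 0; i <= 128; ++i) zf[i] = std::exp(-0.5 * zx[i] * zx[i]);
  zinit = true;
}
static inline double zigg_draw() {
  for (;;) {
    double u0 = unif_rand() * 128.0;
    int i = (int)u0;
    if (i > 127) i = 127;
    double u = 2.0 * (u0 - i) - 1.0;
    double x = u * zx[i];
    if (std::fabs(x) < zx[i + 1]) return x;  // fully inside the layer
    if (i == 0) {                            // tail beyond r
      const double r = 3.442619855899;
      double xx, yy;
      do {
        xx = -std::log(unif_rand()) / r;
        yy = -std::log(unif_rand());
      } while (yy + yy < xx * xx);
      return (u > 0) ? r + xx : -(r + xx);
    }
    if (zf[i] + unif_rand() * (zf[i + 1] - zf[i]) < std::exp(-0.5 * x * x))
      return x;                              // wedge accept
  }
}

// Breathing scene: static base frame S plus a chest rectangle re-sampled each
// frame from appearance patch P shifted vertically by d[t] (bilinear in y),
// plus iid sensor noise. P covers the chest rect with `margin` extra rows
// above and below so |d| <= margin stays in bounds.
// [[Rcpp::export]]
NumericVector cpp_render_breathing(NumericMatrix S, NumericMatrix P,
                                   int chest_x0, int chest_y0,
                                   int chest_w, int chest_h, int margin,
                                   NumericVector d, double sigma) {
  const int nr = S.nrow(), nc = S.ncol(), nf = d.size();
  if (!zinit) zigg_setup();
  NumericVector out(Dimension(nr, nc, nf));
  const R_xlen_t fsz = (R_xlen_t)nr * nc;
  for (int t = 0; t < nf; ++t) {
    double *fr = REAL(out) + (R_xlen_t)t * fsz;
    if (sigma > 0)
      for (R_xlen_t i = 0; i < fsz; ++i) fr[i] = S[i] + sigma * zigg_draw();
    else
      std::copy(S.begin(), S.end(), fr);
    // chest: sample source row r - d(t) from P (row r maps to P row r+margin)
    double dt = d[t];
    for (int c = 0; c < chest_w; ++c) {
      for (int r = 0; r < chest_h; ++r) {
        double src = r - dt + margin;
        int r0 = (int)std::floor(src);
        double w = src - r0;
        if (r0 < 0) { r0 = 0; w = 0.0; }
        if (r0 >= P.nrow() - 1) { r0 = P.nrow() - 2; w = 1.0; }
        double v = (1.0 - w) * P(r0, c) + w * P(r0 + 1, c);
        fr[(R_xlen_t)(chest_x0 + c) * nr + (chest_y0 + r)] =
          v + (sigma > 0 ? sigma * zigg_draw() : 0.0);
      }
    }
  }
  return out;
}

// Open-field scene: warm elliptic body with rigidly advected texture TEX
// (body-frame appearance, already includes body temperature) drawn at centers
// (cx[t], cy[t]) over a uniform background, with a linear partial-volume
// feather of width `feather` px across the ellipse boundary, plus noise.
// [[Rcpp::export]]
NumericVector cpp_render_oft(int nr, int nc, NumericVector cx, NumericVector cy,
                             double ax, double ay, double feather,
                             NumericMatrix TEX, double bg, double sigma,
                             double halo_scale, double halo_c) {
  const int nf = cx.size();
  if (!zinit) zigg_setup();
  NumericVector out(Dimension(nr, nc, nf));
  const R_xlen_t fsz = (R_xlen_t)nr * nc;
  const int th = TEX.nrow(), tw = TEX.ncol();
  const double tcy = (th - 1) / 2.0, tcx = (tw - 1) / 2.0;
  const double rmin = std::min(ax, ay);
  for (int t = 0; t < nf; ++t) {
    double *fr = REAL(out) + (R_xlen_t)t * fsz;
    std::fill(fr, fr + fsz, bg);
    double px = cx[t], py = cy[t];
    const double hs = (halo_scale > 1) ? halo_scale : 1.0;
    const double hfe = 2 * std::max(feather, 1.0);
    int x0 = std::max(0, (int)std::floor(px - ax * hs - hfe - 1));
    int x1 = std::min(nc - 1, (int)std::ceil(px + ax * hs + hfe + 1));
    int y0 = std::max(0, (int)std::floor(py - ay * hs - hfe - 1));
    int y1 = std::min(nr - 1, (int)std::ceil(py + ay * hs + hfe + 1));
    for (int x = x0; x <= x1; ++x) {
      double dx = x - px;
      for (int y = y0; y <= y1; ++y) {
        double dy = y - py;
        double rho = std::sqrt((dx / ax) * (dx / ax) + (dy / ay) * (dy / ay));
        double base = bg;
        if (halo_scale > 1) {  // warm periphery under the core body
          double sh = 0.5 - (rho / halo_scale - 1.0) * rmin * halo_scale / hfe;
          if (sh > 1) sh = 1; else if (sh < 0) sh = 0;
          base = bg + (halo_c - bg) * sh;
          if (base != bg) fr[(R_xlen_t)x * nr + y] = base;
        }
        double s;
        if (feather > 0) {
          double dist = (rho - 1.0) * rmin;  // approx signed px distance
          s = 0.5 - dist / feather;
          if (s < 0) s = 0; else if (s > 1) s = 1;
        } else s = (rho <= 1.0) ? 1.0 : 0.0;
        if (s <= 0) continue;
        // body-frame bilinear sample of appearance
        double sy = dy + tcy, sx = dx + tcx;
        int iy = (int)std::floor(sy), ix = (int)std::floor(sx);
        double wy = sy - iy, wx = sx - ix;
        if (iy < 0) { iy = 0; wy = 0; }
        if (ix < 0) { ix = 0; wx = 0; }
        if (iy >= th - 1) { iy = th - 2; wy = 1; }
        if (ix >= tw - 1) { ix = tw - 2; wx = 1; }
        double a = (1 - wy) * ((1 - wx) * TEX(iy, ix) + wx * TEX(iy, ix + 1)) +
                   wy * ((1 - wx) * TEX(iy + 1, ix) + wx * TEX(iy + 1, ix + 1));
        fr[(R_xlen_t)x * nr + y] = base + (a - base) * s;
      }
    }
    if (sigma > 0)
      for (R_xlen_t i = 0; i < fsz; ++i) fr[i] += sigma * zigg_draw();
  }
  return out;
}
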