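#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- Shi-Tomasi corner response ------------------------------------------
// Min eigenvalue of the gradient structure tensor summed over a
// (2w+1)x(2w+1) box. Sobel gradients; border response is 0.
// [[Rcpp::export]]
NumericMatrix cpp_shi_tomasi(NumericMatrix img, int w) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc), out(nr, nc);
  for (int x = 1; x < nc - 1; ++x)
    for (int y = 1; y < nr - 1; ++y) {
      gx(y, x) = (img(y - 1, x + 1) + 2 * img(y, x + 1) + img(y + 1, x + 1)
                - img(y - 1, x - 1) - 2 * img(y, x - 1) - img(y + 1, x - 1)) / 8.0;
      gy(y, x) = (img(y + 1, x - 1) + 2 * img(y + 1, x) + img(y + 1, x + 1)
                - img(y - 1, x - 1) - 2 * img(y - 1, x) - img(y - 1, x + 1)) / 8.0;
    }
  const int b = w + 1;
  for (int x = b; x < nc - b; ++x)
    for (int y = b; y < nr - b; ++y) {
      double sxx = 0, sxy = 0, syy = 0;
      for (int dx = -w; dx <= w; ++dx)
        for (int dy = -w; dy <= w; ++dy) {
          double ix = gx(y + dy, x + dx), iy = gy(y + dy, x + dx);
          sxx += ix * ix; sxy += ix * iy; syy += iy * iy;
        }
      double tr = sxx + syy;
      double det = std::sqrt((sxx - syy) * (sxx - syy) + 4 * sxy * sxy);
      out(y, x) = 0.5 * (tr - det);
    }
  return out;
}

// ---- Pyramidal Lucas-Kanade ----------------------------------------------
// Image pyramid with per-level central-difference gradient maps, built once
// per frame (not per point).

struct Pyramid {
  std::vector<std::vector<double>> im, gx, gy;
  std::vector<int> nr, nc;
};

static void build_pyramid(const int *img, int nr, int nc, int levels, Pyramid &p) {
  p.im.resize(levels); p.gx.resize(levels); p.gy.resize(levels);
  p.nr.resize(levels); p.nc.resize(levels);
  p.im[0].assign((size_t)nr * nc, 0.0);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i) p.im[0][i] = img[i];
  p.nr[0] = nr; p.nc[0] = nc;
  for (int l = 1; l < levels; ++l) {
    int pr = p.nr[l - 1], pc = p.nc[l - 1];
    int cr = pr / 2, cc = pc / 2;
    p.im[l].assign((size_t)cr * cc, 0.0);
    for (int x = 0; x < cc; ++x)
      for (int y = 0; y < cr; ++y)
        p.im[l][(size_t)x * cr + y] =
          0.25 * (p.im[l - 1][(size_t)(2 * x) * pr + 2 * y] +
                  p.im[l - 1][(size_t)(2 * x + 1) * pr + 2 * y] +
                  p.im[l - 1][(size_t)(2 * x) * pr + 2 * y + 1] +
                  p.im[l - 1][(size_t)(2 * x + 1) * pr + 2 * y + 1]);
    p.nr[l] = cr; p.nc[l] = cc;
  }
  for (int l = 0; l < levels; ++l) {
    int lr = p.nr[l], lc = p.nc[l];
    p.gx[l].assign((size_t)lr * lc, 0.0);
    p.gy[l].assign((size_t)lr * lc, 0.0);
    const double *im = p.im[l].data();
    for (int x = 1; x < lc - 1; ++x)
      for (int y = 1; y < lr - 1; ++y) {
        p.gx[l][(size_t)x * lr + y] =
          0.5 * (im[(size_t)(x + 1) * lr + y] - im[(size_t)(x - 1) * lr + y]);
        p.gy[l][(size_t)x * lr + y] =
          0.5 * (im[(size_t)x * lr + y + 1] - im[(size_t)x * lr + y - 1]);
      }
  }
}

static inline double interp(const std::vector<double> &im, int nr,
                            double x, double y) {
  int ix = (int)x, iy = (int)y;  // callers guarantee x, y >= 1
  double wx = x - ix, wy = y - iy;
  const double *p = im.data() + (size_t)ix * nr + iy;
  return (1 - wy) * ((1 - wx) * p[0] + wx * p[nr]) +
         wy * ((1 - wx) * p[1] + wx * p[nr + 1]);
}

// Track one point from pyramid I to pyramid J. Returns true on success.
static bool lk_point(const Pyramid &I, const Pyramid &J, double x0, double y0,
                     double &x1, double &y1, int w, int max_iter, double eps) {
  int levels = (int)I.im.size();
  const int side = 2 * w + 1;
  std::vector<double> Ix(side * side), Iy(side * side), Iv(side * side);
  double gx = 0, gy = 0;  // guess carried down from coarser levels
  x1 = x0; y1 = y0;
  for (int l = levels - 1; l >= 0; --l) {
    double px = x0 / (1 << l), py = y0 / (1 << l);
    int nr = I.nr[l], nc = I.nc[l];
    if (px - w < 1 || py - w < 1 || px + w > nc - 3 || py + w > nr - 3) {
      if (l == 0) return false;
      gx *= 2; gy *= 2; continue;
    }
    double a11 = 0, a12 = 0, a22 = 0;
    int k = 0;
    for (int dy = -w; dy <= w; ++dy)
      for (int dx = -w; dx <= w; ++dx, ++k) {
        double xx = px + dx, yy = py + dy;
        Iv[k] = interp(I.im[l], nr, xx, yy);
        double ix = interp(I.gx[l], nr, xx, yy);
        double iy = interp(I.gy[l], nr, xx, yy);
        Ix[k] = ix; Iy[k] = iy;
        a11 += ix * ix; a12 += ix * iy; a22 += iy * iy;
      }
    double det = a11 * a22 - a12 * a12;
    if (det < 1e-8 || a11 + a22 < 1e-6) {
      if (l == 0) return false;
      gx *= 2; gy *= 2; continue;
    }
    double vx = gx, vy = gy;
    bool oob = false;
    for (int it = 0; it < max_iter; ++it) {
      double qx = px + vx, qy = py + vy;
      if (qx - w < 1 || qy - w < 1 || qx + w > J.nc[l] - 3 || qy + w > J.nr[l] - 3) {
        oob = true; break;
      }
      double b1 = 0, b2 = 0;
      k = 0;
      for (int dy = -w; dy <= w; ++dy)
        for (int dx = -w; dx <= w; ++dx, ++k) {
          double diff = Iv[k] - interp(J.im[l], J.nr[l], qx + dx, qy + dy);
          b1 += diff * Ix[k]; b2 += diff * Iy[k];
        }
      double ux = (a22 * b1 - a12 * b2) / det;
      double uy = (a11 * b2 - a12 * b1) / det;
      vx += ux; vy += uy;
      if (ux * ux + uy * uy < eps * eps) break;
    }
    if (l == 0 && oob) return false;
    if (l > 0) { gx = 2 * vx; gy = 2 * vy; }
    else { x1 = x0 + vx; y1 = y0 + vy; }
  }
  return (x1 >= 1 && y1 >= 1 && x1 <= J.nc[0] - 2 && y1 <= J.nr[0] - 2);
}

// Track points through an 8-bit (rows, cols, frames) stack.
// x0, y0: 0-based start positions. Returns frames x npts position matrices
// and a validity matrix (once invalid, a point stays invalid).
// [[Rcpp::export]]
List cpp_lk_track(IntegerVector video, NumericVector x0, NumericVector y0,
                  int levels, int w, int max_iter, double eps) {
  IntegerVector dims = video.attr("dim");
  const int nr = dims[0], nc = dims[1], nf = dims[2];
  const int np = x0.size();
  NumericMatrix X(nf, np), Y(nf, np);
  LogicalMatrix V(nf, np);
  for (int j = 0; j < np; ++j) { X(0, j) = x0[j]; Y(0, j) = y0[j]; V(0, j) = true; }
  Pyramid A, B;
  build_pyramid(INTEGER(video), nr, nc, levels, A);
  for (int t = 1; t < nf; ++t) {
    build_pyramid(INTEGER(video) + (R_xlen_t)t * nr * nc, nr, nc, levels, B);
    for (int j = 0; j < np; ++j) {
      if (!V(t - 1, j)) { V(t, j) = false; X(t, j) = NA_REAL; Y(t, j) = NA_REAL; continue; }
      double xn, yn;
      bool ok = lk_point(A, B, X(t - 1, j), Y(t - 1, j), xn, yn, w, max_iter, eps);
      if (ok) { X(t, j) = xn; Y(t, j) = yn; V(t, j) = true; }
      else { X(t, j) = NA_REAL; Y(t, j) = NA_REAL; V(t, j) = false; }
    }
    std::swap(A, B);
  }
  return List::create(_["x"] = X, _["y"] = Y, _["valid"] = V);
}
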