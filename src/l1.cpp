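#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Non-negative l1-regularized least squares over the dictionary [T, I, -I]:
//   min ||y - T a - e||^2 + lambda * (sum(a) + sum|e|),  a >= 0
// where e is the net coefficient of the +/- identity (trivial template)
// pair. Solved by alternating block minimization: coordinate descent on the
// template coefficients a against the templates' Gram matrix, then the
// exact closed-form update of the trivial block (soft threshold of the
// residual). Both blocks are convex with separable penalties, so the
// alternation decreases the objective monotonically to the joint optimum.
// `G` is the m x m Gram matrix T'T (recomputed when NULL); passing it in
// lets a caller score many candidates against one template set cheaply.
static void l1_cd(const double *y, const double *T, int d, int m,
                  double lambda, double tol, int maxit, const double *G_in,
                  std::vector<double> &a, std::vector<double> &e,
                  double &err, double &obj) {
  const double thr = lambda / 2.0;
  std::vector<double> Gloc;
  const double *G = G_in;
  if (G == nullptr) {
    Gloc.assign((size_t)m * m, 0.0);
    for (int j = 0; j < m; ++j)
      for (int k = j; k < m; ++k) {
        double s = 0;
        for (int i = 0; i < d; ++i) s += T[(size_t)j * d + i] * T[(size_t)k * d + i];
        Gloc[(size_t)j * m + k] = Gloc[(size_t)k * m + j] = s;
      }
    G = Gloc.data();
  }
  std::vector<double> c(m), q(m, 0.0), Ta(d, 0.0);
  for (int j = 0; j < m; ++j) {
    double s = 0;
    const double *tj = T + (size_t)j * d;
    for (int i = 0; i < d; ++i) s += tj[i] * y[i];
    c[j] = s;
  }
  a.assign(m, 0.0);
  e.assign(d, 0.0);
  for (int it = 0; it < maxit; ++it) {
    // block 1: CD on template coefficients given e (diag(G) = ||t_j||^2)
    double amax = 0;
    for (int sweep = 0; sweep < 50; ++sweep) {
      amax = 0;
      for (int j = 0; j < m; ++j) {
        const double *gj = G + (size_t)j * m;
        double s = 0;
        for (int k = 0; k < m; ++k) s += gj[k] * a[k];
        double z = a[j] * gj[j] + c[j] - q[j] - s;  // gradient step at a_j
        double nj = (z - thr) / gj[j];
        if (nj < 0) nj = 0;
        double ch = std::fabs(nj - a[j]);
        if (ch > amax) amax = ch;
        a[j] = nj;
      }
      if (amax < tol) break;
    }
    // block 2: exact trivial-template update e = soft(y - Ta, lambda/2)
    for (int i = 0; i < d; ++i) Ta[i] = 0;
    for (int j = 0; j < m; ++j) {
      double aj = a[j];
      if (aj == 0.0) continue;
      const double *tj = T + (size_t)j * d;
      for (int i = 0; i < d; ++i) Ta[i] += tj[i] * aj;
    }
    double emax = 0;
    for (int i = 0; i < d; ++i) {
      double r = y[i] - Ta[i];
      double ne = (r > thr) ? r - thr : (r < -thr ? r + thr : 0.0);
      double ch = std::fabs(ne - e[i]);
      if (ch > emax) emax = ch;
      e[i] = ne;
    }
    if (emax < tol && amax < tol) break;
    for (int j = 0; j < m; ++j) {
      double s = 0;
      const double *tj = T + (size_t)j * d;
      for (int i = 0; i < d; ++i) s += tj[i] * e[i];
      q[j] = s;
    }
  }
  double rss = 0, l1 = 0;
  err = 0;
  for (int i = 0; i < d; ++i) {
    double rt = y[i] - Ta[i];
    err += rt * rt;
    double r = rt - e[i];
    rss += r * r;
    l1 += std::fabs(e[i]);
  }
  for (int j = 0; j < m; ++j) l1 += a[j];
  obj = rss + lambda * l1;
}

// [[Rcpp::export(rng = false)]]
List cpp_l1_solve(NumericVector y, NumericMatrix T, double lambda,
                  double tol, int maxit) {
  std::vector<double> a, e;
  double err, obj;
  l1_cd(REAL(y), REAL(T), T.nrow(), T.ncol(), lambda, tol, maxit, nullptr,
        a, e, err, obj);
  return List::create(_["coef"] = NumericVector(a.begin(), a.end()),
                      _["trivial"] = NumericVector(e.begin(), e.end()),
                      _["error"] = err, _["objective"] = obj);
}

// Bilinear patch extraction from an 8-bit frame: rectangle of size (w, h)
// centered at (cx, cy) (0-based pixel-center coords), resampled to ph x pw.
static void extract_patch(const int *img, int nr, int nc, double cx, double cy,
                          double w, double h, int ph, int pw, double *out) {
  for (int px = 0; px < pw; ++px) {
    double fx = cx + ((pw == 1) ? 0.0 : (px / (double)(pw - 1) - 0.5)) * w;
    for (int py = 0; py < ph; ++py) {
      double fy = cy + ((ph == 1) ? 0.0 : (py / (double)(ph - 1) - 0.5)) * h;
      double x = fx, y = fy;
      if (x < 0) x = 0; if (x > nc - 1) x = nc - 1;
      if (y < 0) y = 0; if (y > nr - 1) y = nr - 1;
      int ix = (int)std::floor(x), iy = (int)std::floor(y);
      if (ix >= nc - 1) ix = nc - 2;
      if (iy >= nr - 1) iy = nr - 2;
      double wx = x - ix, wy = y - iy;
      double v00 = img[(size_t)ix * nr + iy], v10 = img[(size_t)(ix + 1) * nr + iy];
      double v01 = img[(size_t)ix * nr + iy + 1], v11 = img[(size_t)(ix + 1) * nr + iy + 1];
      out[(size_t)px * ph + py] =
        (1 - wy) * ((1 - wx) * v00 + wx * v10) + wy * ((1 - wx) * v01 + wx * v11);
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_extract_patch(IntegerMatrix frame, double cx, double cy,
                                double w, double h, int ph, int pw) {
  NumericVector out((R_xlen_t)ph * pw);
  extract_patch(INTEGER(frame), frame.nrow(), frame.ncol(), cx, cy, w, h, ph, pw,
                REAL(out));
  return out;
}

// Score candidate states against the template set: extract each candidate's
// patch, zero-mean unit-norm it, and return the target-template
// reconstruction error of the l1 solve. Degenerate (zero-variance) patches
// score a fixed error of 2 (the maximum for unit-norm y and empty a).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_score_candidates(IntegerMatrix frame, NumericMatrix states,
                                   double w0, double h0, NumericMatrix T,
                                   double lambda, double tol, int maxit,
                                   int ph, int pw) {
  const int n = states.nrow(), d = ph * pw, m = T.ncol();
  NumericVector errs(n);
  // one Gram matrix for the whole candidate set
  std::vector<double> G((size_t)m * m);
  for (int j = 0; j < m; ++j)
    for (int k = j; k < m; ++k) {
      double s = 0;
      for (int i = 0; i < d; ++i) s += T[(size_t)j * d + i] * T[(size_t)k * d + i];
      G[(size_t)j * m + k] = G[(size_t)k * m + j] = s;
    }
  std::vector<double> patch(d), a, e;
  for (int i = 0; i < n; ++i) {
    double sx = std::exp(states(i, 2)), sy = std::exp(states(i, 3));
    extract_patch(INTEGER(frame), frame.nrow(), frame.ncol(),
                  states(i, 0), states(i, 1), w0 * sx, h0 * sy, ph, pw,
                  patch.data());
    double mean = 0;
    for (int k = 0; k < d; ++k) mean += patch[k];
    mean /= d;
    double nrm = 0;
    for (int k = 0; k < d; ++k) { patch[k] -= mean; nrm += patch[k] * patch[k]; }
    nrm = std::sqrt(nrm);
    if (nrm < 1e-8) { errs[i] = 2.0; continue; }
    for (int k = 0; k < d; ++k) patch[k] /= nrm;
    double err, obj;
    l1_cd(patch.data(), REAL(T), d, m, lambda, tol, maxit, G.data(), a, e,
          err, obj);
    errs[i] = err;
  }
  return errs;
}
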