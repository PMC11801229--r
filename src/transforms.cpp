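#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Transform conventions
// ---------------------
// Affine stage (push-forward, moving -> fixed): a point x_m in the moving
// image lands at x_f = A (x_m - c) + c + b. Resampling therefore evaluates
// out(x_f) = moving(A^{-1}(x_f - c - b) + c). Points are (x, y) with x = column
// index and y = row index, 0-based pixel centers.
//
// B-spline stage (pull-back free-form deformation): out(x) = in(x + u(x))
// where u is a cubic B-spline field over a (mesh_x x mesh_y)-cell grid spanning
// the image domain [0, W-1] x [0, H-1]; control matrices have
// (mesh_y + 3) rows x (mesh_x + 3) columns.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// bilinear sample with outside -> (fill, inside=false)
static inline double sample_bilinear(const NumericMatrix &img, double x, double y,
                                     bool &inside) {
  const int h = img.nrow(), w = img.ncol();
  if (x < 0 || x > w - 1 || y < 0 || y > h - 1) { inside = false; return 0.0; }
  inside = true;
  int j = (int)std::floor(x), i = (int)std::floor(y);
  if (j >= w - 1) j = w - 2 >= 0 ? w - 2 : 0;
  if (i >= h - 1) i = h - 2 >= 0 ? h - 2 : 0;
  double fx = x - j, fy = y - i;
  if (w == 1) { fx = 0; }
  if (h == 1) { fy = 0; }
  double v00 = img(i, j);
  double v01 = (w > 1) ? img(i, j + 1) : v00;
  double v10 = (h > 1) ? img(i + 1, j) : v00;
  double v11 = (w > 1 && h > 1) ? img(i + 1, j + 1) : v00;
  return v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
         v10 * (1 - fx) * fy + v11 * fx * fy;
}

static inline double sample_nearest(const NumericMatrix &img, double x, double y,
                                    bool &inside) {
  const int h = img.nrow(), w = img.ncol();
  long j = (long)std::lround(x), i = (long)std::lround(y);
  if (j < 0 || j >= w || i < 0 || i >= h) { inside = false; return 0.0; }
  inside = true;
  return img((int)i, (int)j);
}

// [[Rcpp::export]]
NumericMatrix affine_resample_cpp(NumericMatrix img,
                                  double a11, double a12, double a21, double a22,
                                  double bx, double by, double cx, double cy,
                                  int interp, int out_h, int out_w) {
  const double det = a11 * a22 - a12 * a21;
  if (det == 0.0) stop("affine matrix is singular");
  const double i11 = a22 / det, i12 = -a12 / det, i21 = -a21 / det, i22 = a11 / det;
  NumericMatrix out(out_h, out_w);
  for (int i = 0; i < out_h; ++i) {
    for (int j = 0; j < out_w; ++j) {
      double dx = j - cx - bx, dy = i - cy - by;
      double sx = i11 * dx + i12 * dy + cx;
      double sy = i21 * dx + i22 * dy + cy;
      bool inside;
      out(i, j) = (interp == 1) ? sample_nearest(img, sx, sy, inside)
                                : sample_bilinear(img, sx, sy, inside);
    }
  }
  return out;
}

// cubic B-spline weights for local coordinate s in [0, 1]
static inline void bspline_w(double s, double *w) {
  const double s2 = s * s, s3 = s2 * s;
  w[0] = (1 - 3 * s + 3 * s2 - s3) / 6.0;
  w[1] = (4 - 6 * s2 + 3 * s3) / 6.0;
  w[2] = (1 + 3 * s + 3 * s2 - 3 * s3) / 6.0;
  w[3] = s3 / 6.0;
}

struct BsplineGrid {
  const NumericMatrix &Px, &Py;
  int mesh_x, mesh_y, W, H;
  double sp_x, sp_y;
  // separable per-axis support (precomputed at integer pixel positions)
  std::vector<int> colIx, rowIy;
  std::vector<double> colW, rowW; // 4 weights per position
  BsplineGrid(const NumericMatrix &px, const NumericMatrix &py,
              int mx, int my, int w, int h)
      : Px(px), Py(py), mesh_x(mx), mesh_y(my), W(w), H(h) {
    sp_x = (W - 1) / (double)mesh_x;
    sp_y = (H - 1) / (double)mesh_y;
    colIx.resize(W); colW.resize(4 * (size_t)W);
    rowIy.resize(H); rowW.resize(4 * (size_t)H);
    for (int j = 0; j < W; ++j) {
      int ix; double wx[4];
      axis_support(j, sp_x, mesh_x, ix, wx);
      colIx[j] = ix;
      for (int a = 0; a < 4; ++a) colW[4 * (size_t)j + a] = wx[a];
    }
    for (int i = 0; i < H; ++i) {
      int iy; double wy[4];
      axis_support(i, sp_y, mesh_y, iy, wy);
      rowIy[i] = iy;
      for (int b = 0; b < 4; ++b) rowW[4 * (size_t)i + b] = wy[b];
    }
  }
  static inline void axis_support(double x, double sp, int mesh, int &ix,
                                  double *wx) {
    double t = x / sp;
    ix = (int)std::floor(t);
    if (ix > mesh - 1) ix = mesh - 1;
    if (ix < 0) ix = 0;
    bspline_w(clampd(t - ix, 0.0, 1.0), wx);
  }
  // local support info for arbitrary (x, y)
  inline void support(double x, double y, int &ix, int &iy,
                      double *wx, double *wy) const {
    axis_support(x, sp_x, mesh_x, ix, wx);
    axis_support(y, sp_y, mesh_y, iy, wy);
  }
  inline void displacement(double x, double y, double &ux, double &uy) const {
    int ix, iy; double wx[4], wy[4];
    support(x, y, ix, iy, wx, wy);
    ux = 0.0; uy = 0.0;
    for (int b = 0; b < 4; ++b)
      for (int a = 0; a < 4; ++a) {
        double wgt = wy[b] * wx[a];
        ux += wgt * Px(iy + b, ix + a);
        uy += wgt * Py(iy + b, ix + a);
      }
  }
  // fast path for integer pixel (j, i) using the precomputed tables
  inline void displacement_px(int j, int i, double &ux, double &uy) const {
    const int ix = colIx[j], iy = rowIy[i];
    const double *wx = &colW[4 * (size_t)j], *wy = &rowW[4 * (size_t)i];
    ux = 0.0; uy = 0.0;
    for (int b = 0; b < 4; ++b) {
      double wyb = wy[b];
      for (int a = 0; a < 4; ++a) {
        double wgt = wyb * wx[a];
        ux += wgt * Px(iy + b, ix + a);
        uy += wgt * Py(iy + b, ix + a);
      }
    }
  }
};

// [[Rcpp::export]]
List bspline_displacement_cpp(NumericMatrix Px, NumericMatrix Py,
                              int mesh_x, int mesh_y, int H, int W) {
  BsplineGrid g(Px, Py, mesh_x, mesh_y, W, H);
  NumericMatrix ux(H, W), uy(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double dx, dy;
      g.displacement_px(j, i, dx, dy);
      ux(i, j) = dx; uy(i, j) = dy;
    }
  return List::create(_["ux"] = ux, _["uy"] = uy);
}

// [[Rcpp::export]]
NumericMatrix bspline_resample_cpp(NumericMatrix img, NumericMatrix Px,
                                   NumericMatrix Py, int mesh_x, int mesh_y,
                                   int interp) {
  const int H = img.nrow(), W = img.ncol();
  BsplineGrid g(Px, Py, mesh_x, mesh_y, W, H);
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double ux, uy;
      g.displacement_px(j, i, ux, uy);
      bool inside;
      out(i, j) = (interp == 1) ? sample_nearest(img, j + ux, i + uy, inside)
                                : sample_bilinear(img, j + ux, i + uy, inside);
    }
  return out;
}

// ---------------------------------------------------------------------------
// Metrics
// ---------------------------------------------------------------------------

// Mutual information of paired samples via a joint histogram with first-order
// (linear) Parzen windows on both axes; returns the *negated* MI in nats.
static double mi_pairs(const std::vector<double> &f, const std::vector<double> &m,
                       int bins) {
  const size_t n = f.size();
  if (n == 0) return 0.0;
  double fmin = f[0], fmax = f[0], mmin = m[0], mmax = m[0];
  for (size_t k = 1; k < n; ++k) {
    if (f[k] < fmin) fmin = f[k];
    if (f[k] > fmax) fmax = f[k];
    if (m[k] < mmin) mmin = m[k];
    if (m[k] > mmax) mmax = m[k];
  }
  if (fmax <= fmin || mmax <= mmin) return 0.0; // constant image: no information
  const double fs = (bins - 1) / (fmax - fmin), ms = (bins - 1) / (mmax - mmin);
  std::vector<double> J((size_t)bins * bins, 0.0);
  for (size_t k = 0; k < n; ++k) {
    double xf = (f[k] - fmin) * fs, xm = (m[k] - mmin) * ms;
    int bf = (int)std::floor(xf), bm = (int)std::floor(xm);
    if (bf >= bins - 1) bf = bins - 2;
    if (bm >= bins - 1) bm = bins - 2;
    double wf = xf - bf, wm = xm - bm;
    J[bf + bins * bm] += (1 - wf) * (1 - wm);
    J[bf + 1 + bins * bm] += wf * (1 - wm);
    J[bf + bins * (bm + 1)] += (1 - wf) * wm;
    J[bf + 1 + bins * (bm + 1)] += wf * wm;
  }
  std::vector<double> Pf(bins, 0.0), Pm(bins, 0.0);
  double tot = (double)n;
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = J[a + bins * b] / tot;
      J[a + bins * b] = p;
      Pf[a] += p; Pm[b] += p;
    }
  double mi = 0.0;
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = J[a + bins * b];
      if (p > 0 && Pf[a] > 0 && Pm[b] > 0) mi += p * std::log(p / (Pf[a] * Pm[b]));
    }
  return -mi;
}

// [[Rcpp::export]]
double mattes_mi_cpp(NumericMatrix fixed, NumericMatrix moving, int bins,
                     Nullable<LogicalMatrix> mask) {
  const int h = fixed.nrow(), w = fixed.ncol();
  std::vector<double> f, m;
  f.reserve((size_t)h * w); m.reserve((size_t)h * w);
  if (mask.isNotNull()) {
    LogicalMatrix mk(mask);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        if (mk(i, j)) { f.push_back(fixed(i, j)); m.push_back(moving(i, j)); }
  } else {
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) { f.push_back(fixed(i, j)); m.push_back(moving(i, j)); }
  }
  return mi_pairs(f, m, bins);
}

// Affine metric evaluation: warp moving by the push-forward affine, collect
// (fixed, warped) pairs over in-mask pixels whose source point lies inside the
// moving image, return negated MI.
// [[Rcpp::export]]
double mi_affine_metric_cpp(NumericMatrix fixed, NumericMatrix moving,
                            double a11, double a12, double a21, double a22,
                            double bx, double by, double cx, double cy,
                            int bins, Nullable<LogicalMatrix> mask) {
  const int h = fixed.nrow(), w = fixed.ncol();
  const double det = a11 * a22 - a12 * a21;
  if (det == 0.0) return NA_REAL;
  const double i11 = a22 / det, i12 = -a12 / det, i21 = -a21 / det, i22 = a11 / det;
  LogicalMatrix mk;
  bool has_mask = mask.isNotNull();
  if (has_mask) mk = LogicalMatrix(mask);
  std::vector<double> f, m;
  f.reserve((size_t)h * w); m.reserve((size_t)h * w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      if (has_mask && !mk(i, j)) continue;
      double dx = j - cx - bx, dy = i - cy - by;
      double sx = i11 * dx + i12 * dy + cx;
      double sy = i21 * dx + i22 * dy + cy;
      bool inside;
      double v = sample_bilinear(moving, sx, sy, inside);
      if (!inside) continue;
      f.push_back(fixed(i, j));
      m.push_back(v);
    }
  return mi_pairs(f, m, bins);
}

// Mean local normalized cross-correlation over (2r+1)^2 windows clipped at the
// image border; windows with < 2 usable pixels or zero variance in either
// image are excluded. Returns the negated mean (perfect match -> -1).
// [[Rcpp::export]]
double ncc_local_cpp(NumericMatrix fixed, NumericMatrix moving, int radius,
                     Nullable<LogicalMatrix> mask) {
  const int h = fixed.nrow(), w = fixed.ncol();
  if (h < 2 * radius + 1 || w < 2 * radius + 1)
    stop("image smaller than the correlation window");
  LogicalMatrix mk;
  bool has_mask = mask.isNotNull();
  if (has_mask) mk = LogicalMatrix(mask);
  double acc = 0.0;
  long cnt = 0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      if (has_mask && !mk(i, j)) continue;
      int i0 = std::max(0, i - radius), i1 = std::min(h - 1, i + radius);
      int j0 = std::max(0, j - radius), j1 = std::min(w - 1, j + radius);
      double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0; int n = 0;
      for (int ii = i0; ii <= i1; ++ii)
        for (int jj = j0; jj <= j1; ++jj) {
          if (has_mask && !mk(ii, jj)) continue;
          double fv = fixed(ii, jj), mv = moving(ii, jj);
          sf += fv; sm += mv; sff += fv * fv; smm += mv * mv; sfm += fv * mv;
          ++n;
        }
      if (n < 2) continue;
      double vf = sff - sf * sf / n, vm = smm - sm * sm / n;
      if (vf <= 1e-12 || vm <= 1e-12) continue;
      acc += (sfm - sf * sm / n) / std::sqrt(vf * vm);
      ++cnt;
    }
  if (cnt == 0) return 0.0;
  return -acc / cnt;
}

// ---------------------------------------------------------------------------
// B-spline stage: metric value and analytic gradient w.r.t. control points.
//
// warped(x) = moving(x + u(x)). dE/dP = sum_x dE/dwarped(x) * grad(moving)(x+u)
//            * basis_weight(x -> P).
// metric 0 = negated mean local NCC (radius), metric 1 = negated MI (bins).
// Samples mapping outside the moving image are excluded from the metric.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List bspline_metric_value_grad_cpp(NumericMatrix fixed, NumericMatrix moving,
                                   NumericMatrix Px, NumericMatrix Py,
                                   int mesh_x, int mesh_y, int metric,
                                   int radius, int bins,
                                   Nullable<LogicalMatrix> mask,
                                   bool want_grad) {
  const int h = fixed.nrow(), w = fixed.ncol();
  BsplineGrid g(Px, Py, mesh_x, mesh_y, w, h);
  LogicalMatrix mk;
  bool has_mask = mask.isNotNull();
  if (has_mask) mk = LogicalMatrix(mask);

  // warp + sampled moving-image partial derivatives
  NumericMatrix warped(h, w), dMx(h, w), dMy(h, w);
  LogicalMatrix ok(h, w);
  // central-difference partials of moving
  NumericMatrix mgx(h, w), mgy(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      int jm = j > 0 ? j - 1 : 0, jp = j < w - 1 ? j + 1 : w - 1;
      int im = i > 0 ? i - 1 : 0, ip = i < h - 1 ? i + 1 : h - 1;
      mgx(i, j) = (moving(i, jp) - moving(i, jm)) / (double)(jp - jm ? jp - jm : 1);
      mgy(i, j) = (moving(ip, j) - moving(im, j)) / (double)(ip - im ? ip - im : 1);
    }
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double ux, uy;
      g.displacement_px(j, i, ux, uy);
      bool inside;
      double v = sample_bilinear(moving, j + ux, i + uy, inside);
      bool use = inside && (!has_mask || mk(i, j));
      ok(i, j) = use;
      warped(i, j) = inside ? v : 0.0;
      if (use && want_grad) {
        bool dummy;
        dMx(i, j) = sample_bilinear(mgx, j + ux, i + uy, dummy);
        dMy(i, j) = sample_bilinear(mgy, j + ux, i + uy, dummy);
      }
    }

  double value = 0.0;
  NumericMatrix gimg(h, w); // dE/dwarped

  if (metric == 0) { // local NCC via integral images (O(N))
    const size_t N = (size_t)h * w;
    auto II = [&](std::vector<double> &s) { s.assign((size_t)(h + 1) * (w + 1), 0.0); };
    std::vector<double> i1v, ifv, imv, iffv, immv, ifmv;
    II(i1v); II(ifv); II(imv); II(iffv); II(immv); II(ifmv);
    auto at = [&](std::vector<double> &s, int i, int j) -> double & {
      return s[(size_t)i * (w + 1) + j];
    };
    for (int i = 0; i < h; ++i)
      for (int j = 0; j < w; ++j) {
        double o = ok(i, j) ? 1.0 : 0.0;
        double fv = o * fixed(i, j), mv = o * warped(i, j);
        at(i1v, i + 1, j + 1) = o;
        at(ifv, i + 1, j + 1) = fv;
        at(imv, i + 1, j + 1) = mv;
        at(iffv, i + 1, j + 1) = fv * fixed(i, j);
        at(immv, i + 1, j + 1) = mv * warped(i, j);
        at(ifmv, i + 1, j + 1) = fv * warped(i, j);
      }
    for (auto *s : {&i1v, &ifv, &imv, &iffv, &immv, &ifmv})
      for (int i = 1; i <= h; ++i)
        for (int j = 1; j <= w; ++j)
          at(*s, i, j) += at(*s, i - 1, j) + at(*s, i, j - 1) - at(*s, i - 1, j - 1);
    auto box = [&](std::vector<double> &s, int i0, int j0, int i1_, int j1_) {
      return at(s, i1_ + 1, j1_ + 1) - at(s, i0, j1_ + 1) -
             at(s, i1_ + 1, j0) + at(s, i0, j0);
    };
    // per-window coefficient fields at window centers
    std::vector<double> cA(N, 0.0), cAf(N, 0.0), cE(N, 0.0), cEm(N, 0.0);
    double acc = 0.0; long cnt = 0;
    for (int i = 0; i < h; ++i) {
      int i0 = std::max(0, i - radius), i1_ = std::min(h - 1, i + radius);
      for (int j = 0; j < w; ++j) {
        if (!ok(i, j)) continue;
        int j0 = std::max(0, j - radius), j1_ = std::min(w - 1, j + radius);
        double n = box(i1v, i0, j0, i1_, j1_);
        if (n < 2) continue;
        double sf = box(ifv, i0, j0, i1_, j1_), sm = box(imv, i0, j0, i1_, j1_);
        double fbar = sf / n, mbar = sm / n;
        double vf = box(iffv, i0, j0, i1_, j1_) - sf * fbar;
        double vm = box(immv, i0, j0, i1_, j1_) - sm * mbar;
        // threshold well above the cancellation error of the cumulative sums,
        // so numerically flat windows cannot inject 1/sqrt(vf*vm) noise
        if (vf <= 1e-6 || vm <= 1e-6) continue;
        double denom = std::sqrt(vf * vm);
        double ncc = (box(ifmv, i0, j0, i1_, j1_) - sf * mbar) / denom;
        acc += ncc; ++cnt;
        if (want_grad) {
          size_t k = (size_t)i * w + j;
          double A = 1.0 / denom, E = ncc / vm;
          cA[k] = A; cAf[k] = A * fbar; cE[k] = E; cEm[k] = E * mbar;
        }
      }
    }
    if (cnt == 0) {
      value = 0.0;
    } else {
      value = -acc / cnt;
      if (want_grad) {
        // box-sum the coefficient fields over each pixel's containing windows
        std::vector<double> iA, iAf, iE, iEm;
        II(iA); II(iAf); II(iE); II(iEm);
        for (int i = 0; i < h; ++i)
          for (int j = 0; j < w; ++j) {
            size_t k = (size_t)i * w + j;
            at(iA, i + 1, j + 1) = cA[k];
            at(iAf, i + 1, j + 1) = cAf[k];
            at(iE, i + 1, j + 1) = cE[k];
            at(iEm, i + 1, j + 1) = cEm[k];
          }
        for (auto *s : {&iA, &iAf, &iE, &iEm})
          for (int i = 1; i <= h; ++i)
            for (int j = 1; j <= w; ++j)
              at(*s, i, j) += at(*s, i - 1, j) + at(*s, i, j - 1) - at(*s, i - 1, j - 1);
        double sc = -1.0 / cnt;
        for (int i = 0; i < h; ++i) {
          int i0 = std::max(0, i - radius), i1_ = std::min(h - 1, i + radius);
          for (int j = 0; j < w; ++j) {
            if (!ok(i, j)) { gimg(i, j) = 0.0; continue; }
            int j0 = std::max(0, j - radius), j1_ = std::min(w - 1, j + radius);
            double SA = box(iA, i0, j0, i1_, j1_);
            double SAf = box(iAf, i0, j0, i1_, j1_);
            double SE = box(iE, i0, j0, i1_, j1_);
            double SEm = box(iEm, i0, j0, i1_, j1_);
            gimg(i, j) = sc * (fixed(i, j) * SA - SAf -
                               warped(i, j) * SE + SEm);
          }
        }
      }
    }
  } else { // MI with linear Parzen windows
    std::vector<double> fv, mv; std::vector<int> is, js;
    fv.reserve((size_t)h * w); mv.reserve((size_t)h * w);
    for (int i = 0; i < h; ++i)
      for (int j = 0; j < w; ++j)
        if (ok(i, j)) { fv.push_back(fixed(i, j)); mv.push_back(warped(i, j));
                        is.push_back(i); js.push_back(j); }
    const size_t n = fv.size();
    if (n == 0) {
      value = 0.0;
    } else {
      double fmin = fv[0], fmax = fv[0], mmin = mv[0], mmax = mv[0];
      for (size_t k = 1; k < n; ++k) {
        fmin = std::min(fmin, fv[k]); fmax = std::max(fmax, fv[k]);
        mmin = std::min(mmin, mv[k]); mmax = std::max(mmax, mv[k]);
      }
      if (fmax <= fmin || mmax <= mmin) {
        value = 0.0;
      } else {
        const double fs = (bins - 1) / (fmax - fmin), ms = (bins - 1) / (mmax - mmin);
        std::vector<double> J((size_t)bins * bins, 0.0);
        for (size_t k = 0; k < n; ++k) {
          double xf = (fv[k] - fmin) * fs, xm = (mv[k] - mmin) * ms;
          int bf = std::min((int)std::floor(xf), bins - 2);
          int bm = std::min((int)std::floor(xm), bins - 2);
          double wf = xf - bf, wm = xm - bm;
          J[bf + bins * bm] += (1 - wf) * (1 - wm);
          J[bf + 1 + bins * bm] += wf * (1 - wm);
          J[bf + bins * (bm + 1)] += (1 - wf) * wm;
          J[bf + 1 + bins * (bm + 1)] += wf * wm;
        }
        std::vector<double> Pm(bins, 0.0);
        for (int b = 0; b < bins; ++b)
          for (int a = 0; a < bins; ++a) { J[a + bins * b] /= n; Pm[b] += J[a + bins * b]; }
        std::vector<double> Pf(bins, 0.0);
        for (int b = 0; b < bins; ++b)
          for (int a = 0; a < bins; ++a) Pf[a] += J[a + bins * b];
        double mi = 0.0;
        for (int b = 0; b < bins; ++b)
          for (int a = 0; a < bins; ++a) {
            double p = J[a + bins * b];
            if (p > 0 && Pf[a] > 0 && Pm[b] > 0) mi += p * std::log(p / (Pf[a] * Pm[b]));
          }
        value = -mi;
        if (want_grad) {
          // d(-MI)/dm_k = -(1/n) sum_{a,b} wf_a * dwm_b/dm * log(J_ab / Pm_b)
          for (size_t k = 0; k < n; ++k) {
            double xf = (fv[k] - fmin) * fs, xm = (mv[k] - mmin) * ms;
            int bf = std::min((int)std::floor(xf), bins - 2);
            int bm = std::min((int)std::floor(xm), bins - 2);
            double wf = xf - bf;
            double gsum = 0.0;
            for (int da = 0; da <= 1; ++da) {
              double wa = da ? wf : 1 - wf;
              if (wa <= 0) continue;
              for (int db = 0; db <= 1; ++db) {
                double dw = (db ? 1.0 : -1.0) * ms; // dwm/dm for bin bm+db
                double p = J[bf + da + bins * (bm + db)];
                double pm = Pm[bm + db];
                if (p > 0 && pm > 0) gsum += wa * dw * std::log(p / pm);
              }
            }
            gimg(is[k], js[k]) = -gsum / (double)n;
          }
        }
      }
    }
  }

  if (!want_grad)
    return List::create(_["value"] = value);

  const int gy = mesh_y + 3, gx = mesh_x + 3;
  NumericMatrix gPx(gy, gx), gPy(gy, gx);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      if (!ok(i, j)) continue;
      double gv = gimg(i, j);
      if (gv == 0.0) continue;
      const int ix = g.colIx[j], iy = g.rowIy[i];
      const double *wx = &g.colW[4 * (size_t)j], *wy = &g.rowW[4 * (size_t)i];
      double gvx = gv * dMx(i, j), gvy = gv * dMy(i, j);
      for (int b = 0; b < 4; ++b)
        for (int a = 0; a < 4; ++a) {
          double wgt = wy[b] * wx[a];
          gPx(iy + b, ix + a) += wgt * gvx;
          gPy(iy + b, ix + a) += wgt * gvy;
        }
    }
  return List::create(_["value"] = value, _["gPx"] = gPx, _["gPy"] = gPy);
}
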