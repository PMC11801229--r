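#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Images are R matrices: (row, col) = (y, x), 0-based coordinates at the C++
// level with pixel centers at integer positions.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 1D resample of every row/column: area averaging when shrinking, linear
// interpolation (pixel-center aligned) when enlarging.
static void resize_1d(const std::vector<double> &in, std::vector<double> &out) {
  const int n_in = (int)in.size(), n_out = (int)out.size();
  if (n_in == n_out) { out = in; return; }
  if (n_out < n_in) {               // box/area average
    const double s = (double)n_in / n_out;
    for (int k = 0; k < n_out; ++k) {
      double lo = k * s, hi = (k + 1) * s, acc = 0.0;
      int i0 = (int)std::floor(lo), i1 = (int)std::ceil(hi);
      if (i1 > n_in) i1 = n_in;
      for (int i = i0; i < i1; ++i) {
        double a = std::max(lo, (double)i), b = std::min(hi, (double)(i + 1));
        if (b > a) acc += in[i] * (b - a);
      }
      out[k] = acc / s;
    }
  } else {                          // linear upscale
    const double s = (double)n_in / n_out;
    for (int k = 0; k < n_out; ++k) {
      double x = (k + 0.5) * s - 0.5;
      x = clampd(x, 0.0, n_in - 1.0);
      int i = (int)std::floor(x);
      if (i >= n_in - 1) i = n_in - 2 >= 0 ? n_in - 2 : 0;
      double f = x - i;
      out[k] = (n_in == 1) ? in[0] : in[i] * (1.0 - f) + in[i + 1] * f;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix resize_image_cpp(NumericMatrix img, int out_h, int out_w) {
  const int h = img.nrow(), w = img.ncol();
  // pass 1: rows -> out_w
  NumericMatrix tmp(h, out_w);
  std::vector<double> rin(w), rout(out_w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) rin[j] = img(i, j);
    resize_1d(rin, rout);
    for (int j = 0; j < out_w; ++j) tmp(i, j) = rout[j];
  }
  // pass 2: cols -> out_h
  NumericMatrix out(out_h, out_w);
  std::vector<double> cin(h), cout_(out_h);
  for (int j = 0; j < out_w; ++j) {
    for (int i = 0; i < h; ++i) cin[i] = tmp(i, j);
    resize_1d(cin, cout_);
    for (int i = 0; i < out_h; ++i) out(i, j) = cout_[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix resize_nearest_cpp(NumericMatrix img, int out_h, int out_w) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  for (int i = 0; i < out_h; ++i) {
    int si = (int)std::floor((i + 0.5) * (double)h / out_h);
    if (si >= h) si = h - 1;
    for (int j = 0; j < out_w; ++j) {
      int sj = (int)std::floor((j + 0.5) * (double)w / out_w);
      if (sj >= w) sj = w - 1;
      out(i, j) = img(si, sj);
    }
  }
  return out;
}

// Sobel gradient magnitude with replicate borders.
// [[Rcpp::export]]
NumericMatrix sobel_cpp(NumericMatrix img) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  for (int i = 0; i < h; ++i) {
    int im = i > 0 ? i - 1 : 0, ip = i < h - 1 ? i + 1 : h - 1;
    for (int j = 0; j < w; ++j) {
      int jm = j > 0 ? j - 1 : 0, jp = j < w - 1 ? j + 1 : w - 1;
      double gx = (img(im, jp) + 2.0 * img(i, jp) + img(ip, jp)) -
                  (img(im, jm) + 2.0 * img(i, jm) + img(ip, jm));
      double gy = (img(ip, jm) + 2.0 * img(ip, j) + img(ip, jp)) -
                  (img(im, jm) + 2.0 * img(im, j) + img(im, jp));
      out(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;
  return k;
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Separable Gaussian blur, mirrored borders. sigma <= 0 returns the input.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  if (sigma <= 0) return clone(img);
  const int h = img.nrow(), w = img.ncol();
  std::vector<double> k = gauss_kernel(sigma);
  const int r = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * img(i, mirror_idx(j + d, w));
      tmp(i, j) = acc;
    }
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(mirror_idx(i + d, h), j);
      out(i, j) = acc;
    }
  return out;
}

// Separable Gaussian blur of a 3D array (dim = c(n1, n2, n3)).
// [[Rcpp::export]]
NumericVector gaussian_blur3d_cpp(NumericVector arr, double sigma) {
  IntegerVector dim = arr.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  if (sigma <= 0) return clone(arr);
  std::vector<double> k = gauss_kernel(sigma);
  const int r = ((int)k.size() - 1) / 2;
  NumericVector a = clone(arr), b(arr.size());
  auto idx = [&](int i, int j, int l) { return i + n1 * (j + n2 * l); };
  // axis 1
  for (int l = 0; l < n3; ++l)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) acc += k[d + r] * a[idx(mirror_idx(i + d, n1), j, l)];
        b[idx(i, j, l)] = acc;
      }
  // axis 2
  for (int l = 0; l < n3; ++l)
    for (int i = 0; i < n1; ++i)
      for (int j = 0; j < n2; ++j) {
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) acc += k[d + r] * b[idx(i, mirror_idx(j + d, n2), l)];
        a[idx(i, j, l)] = acc;
      }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i)
      for (int l = 0; l < n3; ++l) {
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) acc += k[d + r] * a[idx(i, j, mirror_idx(l + d, n3))];
        b[idx(i, j, l)] = acc;
      }
  b.attr("dim") = dim;
  return b;
}

// Oblique plane sampling of a 3D volume (dims: AP, DV, LR).
// Plane through p0 = (ap, (n2-1)/2, (n3-1)/2); in-plane axes u (columns) and v
// (rows) given as 3-vectors in (AP, DV, LR) components. Linear interpolation
// when interp == 0, nearest-neighbor when interp == 1; outside the volume -> 0.
// [[Rcpp::export]]
NumericMatrix slice_volume_cpp(NumericVector vol, double ap,
                               NumericVector u, NumericVector v,
                               int interp) {
  IntegerVector dim = vol.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int H = n2, W = n3;
  const double c1 = ap, c2 = (n2 - 1) / 2.0, c3 = (n3 - 1) / 2.0;
  auto idx = [&](int i, int j, int l) { return i + n1 * ((size_t)j + (size_t)n2 * l); };
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    double dv = i - (H - 1) / 2.0;
    for (int j = 0; j < W; ++j) {
      double du = j - (W - 1) / 2.0;
      double p1 = c1 + du * u[0] + dv * v[0];
      double p2 = c2 + du * u[1] + dv * v[1];
      double p3 = c3 + du * u[2] + dv * v[2];
      if (interp == 1) {
        long i1 = (long)std::lround(p1), i2 = (long)std::lround(p2), i3 = (long)std::lround(p3);
        if (i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2 || i3 < 0 || i3 >= n3) {
          out(i, j) = 0.0;
        } else out(i, j) = vol[idx((int)i1, (int)i2, (int)i3)];
      } else {
        if (p1 < 0 || p1 > n1 - 1 || p2 < 0 || p2 > n2 - 1 || p3 < 0 || p3 > n3 - 1) {
          out(i, j) = 0.0; continue;
        }
        int a = (int)std::floor(p1), b = (int)std::floor(p2), c = (int)std::floor(p3);
        if (a >= n1 - 1) a = n1 - 2 >= 0 ? n1 - 2 : 0;
        if (b >= n2 - 1) b = n2 - 2 >= 0 ? n2 - 2 : 0;
        if (c >= n3 - 1) c = n3 - 2 >= 0 ? n3 - 2 : 0;
        double fa = p1 - a, fb = p2 - b, fc = p3 - c;
        double acc = 0.0;
        for (int da = 0; da <= 1; ++da)
          for (int db = 0; db <= 1; ++db)
            for (int dc = 0; dc <= 1; ++dc) {
              double wgt = (da ? fa : 1 - fa) * (db ? fb : 1 - fb) * (dc ? fc : 1 - fc);
              if (wgt > 0) acc += wgt * vol[idx(a + da, b + db, c + dc)];
            }
        out(i, j) = acc;
      }
    }
  }
  return out;
}

// Local maxima of a difference-of-Gaussians scale stack (list of H x W
// matrices). A maximum must exceed `threshold` and all 26 neighbors in
// (y, x, scale). Returns a matrix with columns (y, x, level, response),
// 0-based indices.
// [[Rcpp::export]]
NumericMatrix dog_local_maxima_cpp(List stack, double threshold) {
  const int L = stack.size();
  std::vector<NumericMatrix> s(L);
  for (int l = 0; l < L; ++l) s[l] = as<NumericMatrix>(stack[l]);
  const int h = s[0].nrow(), w = s[0].ncol();
  std::vector<double> ys, xs, ls, rs;
  for (int l = 0; l < L; ++l) {
    for (int i = 1; i < h - 1; ++i)
      for (int j = 1; j < w - 1; ++j) {
        double v = s[l](i, j);
        if (v <= threshold) continue;
        bool ok = true;
        for (int dl = -1; dl <= 1 && ok; ++dl) {
          if (l + dl < 0 || l + dl >= L) continue;
          for (int di = -1; di <= 1 && ok; ++di)
            for (int dj = -1; dj <= 1 && ok; ++dj) {
              if (dl == 0 && di == 0 && dj == 0) continue;
              if (s[l + dl](i + di, j + dj) >= v) ok = false;
            }
        }
        if (ok) { ys.push_back(i); xs.push_back(j); ls.push_back(l); rs.push_back(v); }
      }
  }
  NumericMatrix out(ys.size(), 4);
  for (size_t k = 0; k < ys.size(); ++k) {
    out(k, 0) = ys[k]; out(k, 1) = xs[k]; out(k, 2) = ls[k]; out(k, 3) = rs[k];
  }
  return out;
}

// Directed Hausdorff distance h(A, B) = max_a min_b ||a - b||.
// Points as two-column matrices (x, y).
// [[Rcpp::export]]
double directed_hausdorff_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  double hmax = 0.0;
  for (int i = 0; i < na; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < dmin) dmin = d2;
      if (dmin <= hmax * hmax) break; // cannot raise the max
    }
    if (dmin > hmax * hmax) hmax = std::sqrt(dmin);
  }
  return hmax;
}
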