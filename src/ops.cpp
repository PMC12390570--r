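// Numerical kernels: im2col GEMM convolution (forward/backward), bilinear
// resize, max-pooling, RoIAlign, tube rasterization, skeleton thinning and
// geodesic length. Tensors are R arrays in (H, W, C, N) layout, column-major.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, int stride,
                   int Ho, int Wo, arma::mat& col) {
  // col: (kh*kw*C) x (Ho*Wo), row index r = i + kh*(j + kw*c)
  col.zeros();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          const double* xcol = x + (size_t)H * (wsrc + (size_t)W * c);
          double* dst = col.memptr() + (size_t)r + (size_t)col.n_rows * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            dst[(size_t)col.n_rows * ho] = xcol[hsrc];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int pad, int stride,
                   int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          double* xcol = gx + (size_t)H * (wsrc + (size_t)W * c);
          const double* src = col.memptr() + (size_t)r + (size_t)col.n_rows * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            xcol[hsrc] += src[(size_t)col.n_rows * ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Ci = dw[2], Co = dw[3];
  if (Ci != C) stop("conv2d: channel mismatch");
  int Ho = out_size(H, kh, pad, stride), Wo = out_size(W, kw, pad, stride);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  NumericVector y(Ho * Wo * Co * (size_t)N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Ci, Co, false, true);
  arma::mat col(kh * kw * Ci, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, stride, Ho, Wo, col);
    arma::mat out(y.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    out = col.t() * Wm;
    for (int c = 0; c < Co; ++c) out.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim"), dy = gy.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Co = dw[3];
  int Ho = dy[0], Wo = dy[1];
  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  gx.attr("dim") = dx; gw.attr("dim") = dw;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Co, false, true);
  arma::mat Gw(gw.begin(), kh * kw * C, Co, false, true);
  arma::mat col(kh * kw * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, stride, Ho, Wo, col);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Co * n,
                 (size_t)Ho * Wo, Co, false, true);
    Gw += col * Gy;
    for (int c = 0; c < Co; ++c) gb[c] += arma::accu(Gy.col(c));
    arma::mat gcol = Wm * Gy.t();
    col2im(gcol, H, W, C, kh, kw, pad, stride, Ho, Wo,
           gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct BilinW { int h0, h1, w0, w1; double a, b; };

static inline void bilin_coef(int dst, int src_n, int dst_n, int& i0, int& i1, double& a) {
  double s = (double)src_n / dst_n;
  double c = (dst + 0.5) * s - 0.5;
  if (c < 0) c = 0;
  if (c > src_n - 1) c = src_n - 1;
  i0 = (int)std::floor(c);
  i1 = std::min(i0 + 1, src_n - 1);
  a = c - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ha(Ho), wa(Wo);
  for (int i = 0; i < Ho; ++i) bilin_coef(i, H, Ho, h0[i], h1[i], ha[i]);
  for (int j = 0; j < Wo; ++j) bilin_coef(j, W, Wo, w0[j], w1[j], wa[j]);
  for (int n = 0; n < N; ++n) for (int c = 0; c < C; ++c) {
    const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
    double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
    for (int j = 0; j < Wo; ++j) for (int i = 0; i < Ho; ++i) {
      double v00 = xs[h0[i] + (size_t)H * w0[j]], v10 = xs[h1[i] + (size_t)H * w0[j]];
      double v01 = xs[h0[i] + (size_t)H * w1[j]], v11 = xs[h1[i] + (size_t)H * w1[j]];
      double top = v00 * (1 - ha[i]) + v10 * ha[i];
      double bot = v01 * (1 - ha[i]) + v11 * ha[i];
      ys[i + (size_t)Ho * j] = top * (1 - wa[j]) + bot * wa[j];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bw(NumericVector gy, int H, int W) {
  IntegerVector dy = gy.attr("dim");
  int Ho = dy[0], Wo = dy[1], C = dy[2], N = dy[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ha(Ho), wa(Wo);
  for (int i = 0; i < Ho; ++i) bilin_coef(i, H, Ho, h0[i], h1[i], ha[i]);
  for (int j = 0; j < Wo; ++j) bilin_coef(j, W, Wo, w0[j], w1[j], wa[j]);
  for (int n = 0; n < N; ++n) for (int c = 0; c < C; ++c) {
    double* xs = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
    const double* ys = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
    for (int j = 0; j < Wo; ++j) for (int i = 0; i < Ho; ++i) {
      double g = ys[i + (size_t)Ho * j];
      xs[h0[i] + (size_t)H * w0[j]] += g * (1 - ha[i]) * (1 - wa[j]);
      xs[h1[i] + (size_t)H * w0[j]] += g * ha[i] * (1 - wa[j]);
      xs[h0[i] + (size_t)H * w1[j]] += g * (1 - ha[i]) * wa[j];
      xs[h1[i] + (size_t)H * w1[j]] += g * ha[i] * wa[j];
    }
  }
  return gx;
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Ho = out_size(H, k, pad, stride), Wo = out_size(W, k, pad, stride);
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n) for (int c = 0; c < C; ++c) {
    const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
    for (int wo = 0; wo < Wo; ++wo) for (int ho = 0; ho < Ho; ++ho) {
      double best = -INFINITY; int bidx = -1;
      for (int j = 0; j < k; ++j) {
        int ws = wo * stride - pad + j;
        if (ws < 0 || ws >= W) continue;
        for (int i = 0; i < k; ++i) {
          int hs = ho * stride - pad + i;
          if (hs < 0 || hs >= H) continue;
          double v = xs[hs + (size_t)H * ws];
          if (v > best) { best = v; bidx = hs + H * ws; }
        }
      }
      size_t out = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
      y[out] = best;
      arg[out] = bidx + (int)((size_t)H * W * (c + (size_t)C * n));
      ++q;
    }
  }
  (void)q;
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector argmax,
                             int H, int W, int C, int N) {
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}

// RoIAlign with 2x2 sampling points per output bin; boxes in feature coords
// after multiplying image-space boxes by `scale`. Boxes: (n x 4) x1,y1,x2,y2.
// [[Rcpp::export]]
NumericVector cpp_roi_align_fw(NumericVector feat, NumericMatrix boxes,
                               int R, double scale) {
  IntegerVector df = feat.attr("dim");
  int H = df[0], W = df[1], C = df[2];
  int nb = boxes.nrow();
  NumericVector y((size_t)R * R * C * nb);
  y.attr("dim") = IntegerVector::create(R, R, C, nb);
  for (int b = 0; b < nb; ++b) {
    double x1 = boxes(b, 0) * scale, y1 = boxes(b, 1) * scale;
    double x2 = boxes(b, 2) * scale, y2 = boxes(b, 3) * scale;
    double bw = std::max(x2 - x1, 1e-3), bh = std::max(y2 - y1, 1e-3);
    double binw = bw / R, binh = bh / R;
    for (int c = 0; c < C; ++c) {
      const double* fs = feat.begin() + (size_t)H * W * c;
      double* ys = y.begin() + (size_t)R * R * (c + (size_t)C * b);
      for (int ox = 0; ox < R; ++ox) for (int oy = 0; oy < R; ++oy) {
        double acc = 0;
        for (int sy = 0; sy < 2; ++sy) for (int sx = 0; sx < 2; ++sx) {
          double px = x1 + (ox + (sx + 0.5) / 2.0) * binw;
          double py = y1 + (oy + (sy + 0.5) / 2.0) * binh;
          // bilinear sample at (px, py); pixel centers at integer coords
          if (px < -1 || px > W || py < -1 || py > H) continue;
          double cx = std::min(std::max(px, 0.0), (double)(W - 1));
          double cy = std::min(std::max(py, 0.0), (double)(H - 1));
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy);
          int x1i = std::min(x0 + 1, W - 1), y1i = std::min(y0 + 1, H - 1);
          double ax = cx - x0, ay = cy - y0;
          double v = fs[y0 + (size_t)H * x0] * (1 - ay) * (1 - ax)
                   + fs[y1i + (size_t)H * x0] * ay * (1 - ax)
                   + fs[y0 + (size_t)H * x1i] * (1 - ay) * ax
                   + fs[y1i + (size_t)H * x1i] * ay * ax;
          acc += v;
        }
        ys[oy + (size_t)R * ox] = acc / 4.0;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_roi_align_bw(NumericVector gy, NumericMatrix boxes,
                               int H, int W, int C, int R, double scale) {
  int nb = boxes.nrow();
  NumericVector gx((size_t)H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C, 1);
  for (int b = 0; b < nb; ++b) {
    double x1 = boxes(b, 0) * scale, y1 = boxes(b, 1) * scale;
    double x2 = boxes(b, 2) * scale, y2 = boxes(b, 3) * scale;
    double bw = std::max(x2 - x1, 1e-3), bh = std::max(y2 - y1, 1e-3);
    double binw = bw / R, binh = bh / R;
    for (int c = 0; c < C; ++c) {
      double* fs = gx.begin() + (size_t)H * W * c;
      const double* ys = gy.begin() + (size_t)R * R * (c + (size_t)C * b);
      for (int ox = 0; ox < R; ++ox) for (int oy = 0; oy < R; ++oy) {
        double g = ys[oy + (size_t)R * ox] / 4.0;
        for (int sy = 0; sy < 2; ++sy) for (int sx = 0; sx < 2; ++sx) {
          double px = x1 + (ox + (sx + 0.5) / 2.0) * binw;
          double py = y1 + (oy + (sy + 0.5) / 2.0) * binh;
          if (px < -1 || px > W || py < -1 || py > H) continue;
          double cx = std::min(std::max(px, 0.0), (double)(W - 1));
          double cy = std::min(std::max(py, 0.0), (double)(H - 1));
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy);
          int x1i = std::min(x0 + 1, W - 1), y1i = std::min(y0 + 1, H - 1);
          double ax = cx - x0, ay = cy - y0;
          fs[y0 + (size_t)H * x0] += g * (1 - ay) * (1 - ax);
          fs[y1i + (size_t)H * x0] += g * ay * (1 - ax);
          fs[y0 + (size_t)H * x1i] += g * (1 - ay) * ax;
          fs[y1i + (size_t)H * x1i] += g * ay * ax;
        }
      }
    }
  }
  return gx;
}

// Signed-distance field of a tapered tube along a polyline. poly: (m x 2)
// pixel coordinates (x, y); halfw, shade: per-vertex. Returns, per pixel,
// min over segments of (distance - local halfwidth) and the shade value at
// the nearest covered point. Pixels never touched keep sdist = +inf.
// [[Rcpp::export]]
List cpp_tube_field(int H, int W, NumericMatrix poly,
                    NumericVector halfw, NumericVector shade) {
  NumericMatrix sd(H, W), sh(H, W);
  std::fill(sd.begin(), sd.end(), R_PosInf);
  int m = poly.nrow();
  for (int s = 0; s + 1 < m; ++s) {
    double x0 = poly(s, 0), y0 = poly(s, 1), x1 = poly(s + 1, 0), y1 = poly(s + 1, 1);
    double hw0 = halfw[s], hw1 = halfw[s + 1];
    double sh0 = shade[s], sh1 = shade[s + 1];
    double r = std::max(hw0, hw1) + 2.0;
    int cx0 = std::max(0, (int)std::floor(std::min(x0, x1) - r));
    int cx1 = std::min(W - 1, (int)std::ceil(std::max(x0, x1) + r));
    int cy0 = std::max(0, (int)std::floor(std::min(y0, y1) - r));
    int cy1 = std::min(H - 1, (int)std::ceil(std::max(y0, y1) + r));
    double vx = x1 - x0, vy = y1 - y0;
    double vv = vx * vx + vy * vy;
    for (int px = cx0; px <= cx1; ++px) for (int py = cy0; py <= cy1; ++py) {
      double t = 0;
      if (vv > 0) {
        t = ((px - x0) * vx + (py - y0) * vy) / vv;
        t = std::min(std::max(t, 0.0), 1.0);
      }
      double qx = x0 + t * vx, qy = y0 + t * vy;
      double d = std::sqrt((px - qx) * (px - qx) + (py - qy) * (py - qy));
      double sdist = d - (hw0 + (hw1 - hw0) * t);
      if (sdist < sd(py, px)) {
        sd(py, px) = sdist;
        sh(py, px) = sh0 + (sh1 - sh0) * t;
      }
    }
  }
  return List::create(_["sdist"] = sd, _["shade"] = sh);
}

// Zhang–Suen thinning of a binary mask (rows = y, cols = x).
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix im = clone(mask);
  auto at = [&](int y, int x) -> int {
    if (y < 0 || y >= H || x < 0 || x >= W) return 0;
    return im(y, x);
  };
  bool changed = true;
  std::vector<std::pair<int,int>> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int y = 0; y < H; ++y) for (int x = 0; x < W; ++x) {
        if (!im(y, x)) continue;
        int p2 = at(y - 1, x), p3 = at(y - 1, x + 1), p4 = at(y, x + 1),
            p5 = at(y + 1, x + 1), p6 = at(y + 1, x), p7 = at(y + 1, x - 1),
            p8 = at(y, x - 1), p9 = at(y - 1, x - 1);
        int Bp = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (Bp < 2 || Bp > 6) continue;
        int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) + (p4 == 0 && p5 == 1)
              + (p5 == 0 && p6 == 1) + (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1)
              + (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
        if (A != 1) continue;
        if (pass == 0) {
          if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
        } else {
          if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
        }
        del.push_back({y, x});
      }
      for (auto& p : del) im(p.first, p.second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return im;
}

// 8-connected component labelling of a binary mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dy[8] = {-1,-1,-1,0,0,1,1,1}, dx[8] = {-1,0,1,-1,1,-1,0,1};
  std::vector<std::pair<int,int>> stack;
  for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y) {
    if (!mask(y, x) || lab(y, x)) continue;
    ++next;
    stack.push_back({y, x});
    lab(y, x) = next;
    while (!stack.empty()) {
      auto [cy, cx] = stack.back(); stack.pop_back();
      for (int k = 0; k < 8; ++k) {
        int ny = cy + dy[k], nx = cx + dx[k];
        if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
        if (mask(ny, nx) && !lab(ny, nx)) { lab(ny, nx) = next; stack.push_back({ny, nx}); }
      }
    }
  }
  return lab;
}

// Geodesic diameter of a skeleton under 8-connectivity with unit/sqrt(2)
// steps (double-sweep Dijkstra; exact on tree-shaped skeletons).
// [[Rcpp::export]]
List cpp_skel_geodesic(IntegerMatrix skel) {
  int H = skel.nrow(), W = skel.ncol();
  std::vector<int> ys, xs;
  IntegerMatrix id(H, W);
  std::fill(id.begin(), id.end(), -1);
  for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y)
    if (skel(y, x)) { id(y, x) = (int)ys.size(); ys.push_back(y); xs.push_back(x); }
  int n = (int)ys.size();
  if (n == 0) return List::create(_["length"] = 0.0, _["n_pixels"] = 0,
                                  _["endpoints"] = NumericMatrix(0, 2));
  const int dy[8] = {-1,-1,-1,0,0,1,1,1}, dx[8] = {-1,0,1,-1,1,-1,0,1};
  const double wcost[8] = {M_SQRT2,1,M_SQRT2,1,1,M_SQRT2,1,M_SQRT2};
  auto dijkstra = [&](int src, std::vector<double>& dist) {
    dist.assign(n, R_PosInf);
    std::priority_queue<std::pair<double,int>, std::vector<std::pair<double,int>>,
                        std::greater<std::pair<double,int>>> pq;
    dist[src] = 0; pq.push({0.0, src});
    while (!pq.empty()) {
      auto [d, u] = pq.top(); pq.pop();
      if (d > dist[u] + 1e-12) continue;
      for (int k = 0; k < 8; ++k) {
        int ny = ys[u] + dy[k], nx = xs[u] + dx[k];
        if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
        int v = id(ny, nx);
        if (v < 0) continue;
        double nd = d + wcost[k];
        if (nd < dist[v] - 1e-12) { dist[v] = nd; pq.push({nd, v}); }
      }
    }
  };
  std::vector<double> dist;
  dijkstra(0, dist);
  int u = 0; double best = -1;
  for (int i = 0; i < n; ++i) if (std::isfinite(dist[i]) && dist[i] > best) { best = dist[i]; u = i; }
  dijkstra(u, dist);
  int v = u; best = 0;
  for (int i = 0; i < n; ++i) if (std::isfinite(dist[i]) && dist[i] > best) { best = dist[i]; v = i; }
  // reconstruct the u -> v geodesic to count orthogonal and diagonal steps
  int n_ortho = 0, n_diag = 0;
  int cur = v;
  while (cur != u) {
    int nxt = -1, step = -1;
    for (int k = 0; k < 8; ++k) {
      int ny = ys[cur] + dy[k], nx = xs[cur] + dx[k];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      int w = id(ny, nx);
      if (w < 0) continue;
      if (std::fabs(dist[cur] - wcost[k] - dist[w]) < 1e-9) { nxt = w; step = k; break; }
    }
    if (nxt < 0) break;
    if (wcost[step] > 1.2) ++n_diag; else ++n_ortho;
    cur = nxt;
  }
  NumericMatrix ep(2, 2);
  ep(0, 0) = xs[u]; ep(0, 1) = ys[u];
  ep(1, 0) = xs[v]; ep(1, 1) = ys[v];
  return List::create(_["length"] = best, _["n_pixels"] = n, _["endpoints"] = ep,
                      _["n_ortho"] = n_ortho, _["n_diag"] = n_diag);
}
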