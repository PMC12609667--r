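#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// All feature maps are R arrays with dim (H, W, C, N), column-major (H fastest).
// im2col lays patches out as an M x K matrix, M = Ho*Wo*N (row index
// m = ho + Ho*(wo + Wo*n)) and K = k*k*C (column index kh + k*kw + k*k*c),
// matching the column-major flattening of a (k, k, C, Cout) weight array, so
// convolution is cols %*% matrix(weight, K, Cout).

// [[Rcpp::export]]
NumericMatrix wbs_im2col(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t M = (R_xlen_t)Ho * Wo * N;
  const int K = k * k * C;
  NumericMatrix cols((int)M, K);
  const double* px = x.begin();
  double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const R_xlen_t col = (R_xlen_t)(kh + k * kw + k * k * c);
        double* dst = pc + col * M;
        for (int n = 0; n < N; ++n) {
          const double* src = px + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kw;
            const bool wok = (w >= 0 && w < W);
            R_xlen_t m = (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            for (int ho = 0; ho < Ho; ++ho, ++m) {
              const int h = ho * stride - pad + kh;
              dst[m] = (wok && h >= 0 && h < H) ? src[h + (R_xlen_t)H * w] : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector wbs_col2im(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t M = (R_xlen_t)Ho * Wo * N;
  NumericVector x((R_xlen_t)H * W * C * N);
  const double* pc = cols.begin();
  double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const R_xlen_t col = (R_xlen_t)(kh + k * kw + k * k * c);
        const double* src = pc + col * M;
        for (int n = 0; n < N; ++n) {
          double* dst = px + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            R_xlen_t m = (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            for (int ho = 0; ho < Ho; ++ho, ++m) {
              const int h = ho * stride - pad + kh;
              if (h >= 0 && h < H) dst[h + (R_xlen_t)H * w] += src[m];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// [[Rcpp::export]]
List wbs_maxpool_fwd(NumericVector x, int H, int W, int C, int N,
                     int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  const double* px = x.begin();
  double* po = out.begin();
  int* pa = arg.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* src = px + ((R_xlen_t)n * C + c) * H * W;
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              const double v = src[h + (R_xlen_t)H * w];
              if (v > best) { best = v; besti = base + h + (R_xlen_t)H * w; }
            }
          }
          po[o] = best;
          pa[o] = (int)(besti + 1);  // 1-based into x
        }
      }
    }
  }
  // output laid out (Ho, Wo) within (c, n) blocks, i.e. dim (Ho, Wo, C, N)
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector wbs_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              R_xlen_t n_in) {
  NumericVector dx(n_in);
  const double* pd = dout.begin();
  const int* pa = argmax.begin();
  double* px = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) {
    if (pa[i] > 0) px[pa[i] - 1] += pd[i];  // 0 marks an all-NaN window
  }
  return dx;
}

static inline double clampd(double v, double lo, double hi) {
  if (!R_finite(v)) return lo;  // non-finite coordinates clamp to the border
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear grid sampling. grid has dim (Ho, Wo, 2, N) with normalized
// coordinates in [-1, 1]; slice 1 is x (width), slice 2 is y (height);
// pixel = ((g + 1) * size - 1) / 2 (half-pixel centers); border clamping.
// [[Rcpp::export]]
NumericVector wbs_grid_sample_fwd(NumericVector x, NumericVector grid,
                                  int H, int W, int C, int N, int Ho, int Wo) {
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  const double* px = x.begin();
  const double* pg = grid.begin();
  double* po = out.begin();
  const R_xlen_t gplane = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const double* gx = pg + (R_xlen_t)n * 2 * gplane;
    const double* gy = gx + gplane;
    for (R_xlen_t p = 0; p < gplane; ++p) {
      double fx = clampd(((gx[p] + 1.0) * W - 1.0) / 2.0, 0.0, W - 1.0);
      double fy = clampd(((gy[p] + 1.0) * H - 1.0) / 2.0, 0.0, H - 1.0);
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
      int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      if (x0 > W - 1) x0 = W - 1;
      if (y0 > H - 1) y0 = H - 1;
      const double ax = fx - x0, ay = fy - y0;
      for (int c = 0; c < C; ++c) {
        const double* src = px + ((R_xlen_t)n * C + c) * H * W;
        const double v00 = src[y0 + (R_xlen_t)H * x0];
        const double v01 = src[y0 + (R_xlen_t)H * x1];
        const double v10 = src[y1 + (R_xlen_t)H * x0];
        const double v11 = src[y1 + (R_xlen_t)H * x1];
        po[p + gplane * ((R_xlen_t)n * C + c)] =
          (1 - ay) * ((1 - ax) * v00 + ax * v01) +
          ay * ((1 - ax) * v10 + ax * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
List wbs_grid_sample_bwd(NumericVector x, NumericVector grid, NumericVector dout,
                         int H, int W, int C, int N, int Ho, int Wo) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dgrid((R_xlen_t)Ho * Wo * 2 * N);
  const double* px = x.begin();
  const double* pg = grid.begin();
  const double* pd = dout.begin();
  double* pdx = dx.begin();
  double* pdg = dgrid.begin();
  const R_xlen_t gplane = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const double* gx = pg + (R_xlen_t)n * 2 * gplane;
    const double* gy = gx + gplane;
    double* dgx = pdg + (R_xlen_t)n * 2 * gplane;
    double* dgy = dgx + gplane;
    for (R_xlen_t p = 0; p < gplane; ++p) {
      const double rx = ((gx[p] + 1.0) * W - 1.0) / 2.0;
      const double ry = ((gy[p] + 1.0) * H - 1.0) / 2.0;
      const bool cx = (rx < 0.0 || rx > W - 1.0);
      const bool cy = (ry < 0.0 || ry > H - 1.0);
      const double fx = clampd(rx, 0.0, W - 1.0);
      const double fy = clampd(ry, 0.0, H - 1.0);
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
      int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      if (x0 > W - 1) x0 = W - 1;
      if (y0 > H - 1) y0 = H - 1;
      const double ax = fx - x0, ay = fy - y0;
      double sfx = 0.0, sfy = 0.0;
      for (int c = 0; c < C; ++c) {
        const R_xlen_t off = ((R_xlen_t)n * C + c) * H * W;
        const double* src = px + off;
        double* dst = pdx + off;
        const double g = pd[p + gplane * ((R_xlen_t)n * C + c)];
        const double v00 = src[y0 + (R_xlen_t)H * x0];
        const double v01 = src[y0 + (R_xlen_t)H * x1];
        const double v10 = src[y1 + (R_xlen_t)H * x0];
        const double v11 = src[y1 + (R_xlen_t)H * x1];
        dst[y0 + (R_xlen_t)H * x0] += g * (1 - ay) * (1 - ax);
        dst[y0 + (R_xlen_t)H * x1] += g * (1 - ay) * ax;
        dst[y1 + (R_xlen_t)H * x0] += g * ay * (1 - ax);
        dst[y1 + (R_xlen_t)H * x1] += g * ay * ax;
        sfx += g * ((1 - ay) * (v01 - v00) + ay * (v11 - v10));
        sfy += g * ((1 - ax) * (v10 - v00) + ax * (v11 - v01));
      }
      dgx[p] = cx ? 0.0 : sfx * W / 2.0;
      dgy[p] = cy ? 0.0 : sfy * H / 2.0;
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dgrid.attr("dim") = IntegerVector::create(Ho, Wo, 2, N);
  return List::create(_["dx"] = dx, _["dgrid"] = dgrid);
}

// 3x3 median filter with edge replication, on a single (H, W) matrix.
// [[Rcpp::export]]
NumericMatrix wbs_median3(NumericMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  double v[9];
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      int m = 0;
      for (int dw = -1; dw <= 1; ++dw) {
        const int ww = std::min(std::max(w + dw, 0), W - 1);
        for (int dh = -1; dh <= 1; ++dh) {
          const int hh = std::min(std::max(h + dh, 0), H - 1);
          v[m++] = x(hh, ww);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(h, w) = v[4];
    }
  }
  return out;
}

// Binary 3x3 morphology; out-of-image neighbours are ignored (erosion behaves
// as if padded with 1, dilation as if padded with 0).
// [[Rcpp::export]]
IntegerMatrix wbs_morph3(IntegerMatrix x, bool erode) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix out(H, W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      int v = erode ? 1 : 0;
      for (int dw = -1; dw <= 1 && (erode ? v : !v); ++dw) {
        const int ww = w + dw;
        if (ww < 0 || ww >= W) continue;
        for (int dh = -1; dh <= 1; ++dh) {
          const int hh = h + dh;
          if (hh < 0 || hh >= H) continue;
          if (erode) { if (!x(hh, ww)) { v = 0; break; } }
          else { if (x(hh, ww)) { v = 1; break; } }
        }
      }
      out(h, w) = v;
    }
  }
  return out;
}
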