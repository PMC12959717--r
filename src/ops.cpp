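// Low-level tensor kernels for the segmentation engine.
// Layout convention: activations are R arrays dim c(H, W, C, N), column-major;
// convolution weights are arrays dim c(kh, kw, Cin/groups, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int dim_i(const NumericVector& x, int i) {
  IntegerVector d = x.attr("dim");
  return d[i];
}

// im2col for one image, one channel group.
// x points at the (H,W,Cin,N) array; channels [c0, c0+cg) of image n.
// col is K x P with K = kh*kw*cg, P = Ho*Wo, row index r = i + kh*(j + kw*ci),
// column index p = ho + Ho*wo.
static void im2col(const double* x, int H, int W, int Cin, int n, int c0, int cg,
                   int kh, int kw, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  const long planeHW = (long)H * W;
  for (int ci = 0; ci < cg; ++ci) {
    const double* xc = x + ((long)n * Cin + (c0 + ci)) * planeHW;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j;
          double* dst = col.colptr(0) + r; // strided writes below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col((arma::uword)r, (arma::uword)(ho + Ho * wo)) = 0.0;
            continue;
          }
          const double* xcol = xc + (long)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i;
            col((arma::uword)r, (arma::uword)(ho + Ho * wo)) =
                (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

// col2im scatter-add, inverse layout of im2col.
static void col2im(const arma::mat& col, double* gx, int H, int W, int Cin, int n,
                   int c0, int cg, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  const long planeHW = (long)H * W;
  for (int ci = 0; ci < cg; ++ci) {
    double* gc = gx + ((long)n * Cin + (c0 + ci)) * planeHW;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (long)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i;
            if (hi >= 0 && hi < H)
              gcol[hi] += col((arma::uword)r, (arma::uword)(ho + Ho * wo));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             int stride, int pad, int groups) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), Cin = dim_i(x, 2), N = dim_i(x, 3);
  const int kh = dim_i(w, 0), kw = dim_i(w, 1), cg = dim_i(w, 2), Cout = dim_i(w, 3);
  if (Cin / groups != cg) stop("conv2d: weight/input channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int coutg = Cout / groups;
  const int K = kh * kw * cg;
  const long P = (long)Ho * Wo;
  NumericVector y((long)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, Cin, n, g * cg, cg, kh, kw, stride, pad, Ho, Wo, col);
      const arma::mat Wm(const_cast<double*>(w.begin()) + (long)K * coutg * g,
                         K, coutg, false, true);
      arma::mat out = col.t() * Wm; // P x coutg
      std::memcpy(y.begin() + ((long)n * Cout + (long)g * coutg) * P,
                  out.memptr(), sizeof(double) * P * coutg);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int groups) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), Cin = dim_i(x, 2), N = dim_i(x, 3);
  const int kh = dim_i(w, 0), kw = dim_i(w, 1), cg = dim_i(w, 2), Cout = dim_i(w, 3);
  const int Ho = dim_i(gy, 0), Wo = dim_i(gy, 1);
  const int coutg = Cout / groups;
  const int K = kh * kw * cg;
  const long P = (long)Ho * Wo;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, Cin, n, g * cg, cg, kh, kw, stride, pad, Ho, Wo, col);
      const arma::mat Gm(const_cast<double*>(gy.begin()) +
                             ((long)n * Cout + (long)g * coutg) * P,
                         P, coutg, false, true);
      arma::mat Gwm(gw.begin() + (long)K * coutg * g, K, coutg, false, true);
      Gwm += col * Gm; // K x coutg
      const arma::mat Wm(const_cast<double*>(w.begin()) + (long)K * coutg * g,
                         K, coutg, false, true);
      arma::mat gcol = Wm * Gm.t(); // K x P
      col2im(gcol, gx.begin(), H, W, Cin, n, g * cg, cg, kh, kw, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// 2x2 max pooling with stride 2; returns pooled values and argmax indices
// (1-based linear indices into x) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  long o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xp = x.begin() + (long)cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -INFINITY; long bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const long li = (long)(2 * ho + di) + (long)H * (2 * wo + dj);
            if (xp[li] > best) { best = xp[li]; bi = li; }
          }
        }
        y[(long)ho + (long)Ho * wo + (long)cn * Ho * Wo] = best;
        idx[(long)ho + (long)Ho * wo + (long)cn * Ho * Wo] =
            (int)((long)cn * H * W + bi + 1);
        ++o;
      }
    }
  }
  (void)o;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector gx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (long i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// Adaptive average pooling to (oh, ow) with floor/ceil window bounds.
// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_fwd(NumericVector x, int oh, int ow) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  NumericVector y((long)oh * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xp = x.begin() + (long)cn * H * W;
    double* yp = y.begin() + (long)cn * oh * ow;
    for (int j = 0; j < ow; ++j) {
      const int w0 = (j * W) / ow, w1 = ((j + 1) * W + ow - 1) / ow;
      for (int i = 0; i < oh; ++i) {
        const int h0 = (i * H) / oh, h1 = ((i + 1) * H + oh - 1) / oh;
        double s = 0.0;
        for (int wj = w0; wj < w1; ++wj)
          for (int hi = h0; hi < h1; ++hi) s += xp[(long)hi + (long)H * wj];
        yp[(long)i + (long)oh * j] = s / ((h1 - h0) * (w1 - w0));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_bwd(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int oh = dim_i(gy, 0), ow = dim_i(gy, 1);
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int cn = 0; cn < C * N; ++cn) {
    double* gp = gx.begin() + (long)cn * H * W;
    const double* gyp = gy.begin() + (long)cn * oh * ow;
    for (int j = 0; j < ow; ++j) {
      const int w0 = (j * W) / ow, w1 = ((j + 1) * W + ow - 1) / ow;
      for (int i = 0; i < oh; ++i) {
        const int h0 = (i * H) / oh, h1 = ((i + 1) * H + oh - 1) / oh;
        const double g = gyp[(long)i + (long)oh * j] / ((h1 - h0) * (w1 - w0));
        for (int wj = w0; wj < w1; ++wj)
          for (int hi = h0; hi < h1; ++hi) gp[(long)hi + (long)H * wj] += g;
      }
    }
  }
  return gx;
}

static inline void bilin_coef(int i, int In, double scale, int& i0, int& i1,
                              double& l1) {
  double src = ((double)i + 0.5) * scale - 0.5;
  if (src < 0) src = 0;
  i0 = (int)src;
  if (i0 > In - 1) i0 = In - 1;
  i1 = (i0 + 1 < In) ? i0 + 1 : In - 1;
  l1 = src - i0;
  if (i1 == i0) l1 = 0.0;
}

// Bilinear resize to (oh, ow), corner-excluding alignment (align_corners=FALSE).
// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int oh, int ow) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const double sh = (double)H / oh, sw = (double)W / ow;
  NumericVector y((long)oh * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  std::vector<int> h0(oh), h1(oh), w0(ow), w1(ow);
  std::vector<double> lh(oh), lw(ow);
  for (int i = 0; i < oh; ++i) bilin_coef(i, H, sh, h0[i], h1[i], lh[i]);
  for (int j = 0; j < ow; ++j) bilin_coef(j, W, sw, w0[j], w1[j], lw[j]);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xp = x.begin() + (long)cn * H * W;
    double* yp = y.begin() + (long)cn * oh * ow;
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        const double a = xp[(long)h0[i] + (long)H * w0[j]];
        const double b = xp[(long)h1[i] + (long)H * w0[j]];
        const double c = xp[(long)h0[i] + (long)H * w1[j]];
        const double d = xp[(long)h1[i] + (long)H * w1[j]];
        yp[(long)i + (long)oh * j] =
            (1 - lh[i]) * (1 - lw[j]) * a + lh[i] * (1 - lw[j]) * b +
            (1 - lh[i]) * lw[j] * c + lh[i] * lw[j] * d;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int oh = dim_i(gy, 0), ow = dim_i(gy, 1);
  const double sh = (double)H / oh, sw = (double)W / ow;
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = xdim;
  std::vector<int> h0(oh), h1(oh), w0(ow), w1(ow);
  std::vector<double> lh(oh), lw(ow);
  for (int i = 0; i < oh; ++i) bilin_coef(i, H, sh, h0[i], h1[i], lh[i]);
  for (int j = 0; j < ow; ++j) bilin_coef(j, W, sw, w0[j], w1[j], lw[j]);
  for (int cn = 0; cn < C * N; ++cn) {
    double* gp = gx.begin() + (long)cn * H * W;
    const double* gyp = gy.begin() + (long)cn * oh * ow;
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        const double g = gyp[(long)i + (long)oh * j];
        gp[(long)h0[i] + (long)H * w0[j]] += (1 - lh[i]) * (1 - lw[j]) * g;
        gp[(long)h1[i] + (long)H * w0[j]] += lh[i] * (1 - lw[j]) * g;
        gp[(long)h0[i] + (long)H * w1[j]] += (1 - lh[i]) * lw[j] * g;
        gp[(long)h1[i] + (long)H * w1[j]] += lh[i] * lw[j] * g;
      }
    }
  }
  return gx;
}

// Integer-domain convolution used by the INT8 quantized inference path:
// x and w hold integer values (stored as doubles, exact up to 2^53); the
// accumulator stays exact, emulating int32 accumulation.
// [[Rcpp::export]]
NumericVector cpp_conv2d_int(NumericVector x, NumericVector w,
                             int stride, int pad, int groups) {
  return cpp_conv2d_fwd(x, w, stride, pad, groups);
}
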