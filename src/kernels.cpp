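// Dense numeric kernels for the CNN engine and image resizing.
// Layout convention: activations are column-major R arrays (H, W, C, N);
// convolution weights are (kh, kw, Cin, F). All heavy products go through
// single-precision BLAS gemm via Armadillo; inputs/outputs stay double on
// the R side. Activations (ReLU/sigmoid) are fused into the convolution
// kernels to avoid full-tensor passes in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gather patches of one sample into a (OH*OW) x (kh*kw*C) matrix (patch
// position fastest). pad0 is applied before the origin; stride applies to
// output positions. The stride-1 path uses contiguous block copies.
static void im2colT(const float* x, int H, int W, int C,
                    int kh, int kw, int ph0, int pw0, int stride,
                    int OH, int OW, arma::fmat& colsT) {
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        float* dstcol = colsT.colptr(r);
        if (stride == 1) {
          int off = ki - ph0;
          int o0 = std::max(0, -off), o1 = std::min(OH, H - off);
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow - pw0 + kj;
            float* dst = dstcol + (size_t)OH * ow;
            if (iw < 0 || iw >= W) {
              std::fill(dst, dst + OH, 0.0f);
              continue;
            }
            const float* src = xc + (size_t)iw * H + off;
            if (o0 > 0) std::fill(dst, dst + o0, 0.0f);
            if (o1 > o0) std::copy(src + o0, src + o1, dst + o0);
            if (o1 < OH) std::fill(dst + std::max(o1, 0), dst + OH, 0.0f);
          }
        } else {
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow * stride - pw0 + kj;
            float* dst = dstcol + (size_t)OH * ow;
            if (iw < 0 || iw >= W) {
              std::fill(dst, dst + OH, 0.0f);
              continue;
            }
            const float* xcw = xc + (size_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              int ih = oh * stride - ph0 + ki;
              dst[oh] = (ih >= 0 && ih < H) ? xcw[ih] : 0.0f;
            }
          }
        }
      }
    }
  }
}

// Scatter-add inverse of im2colT.
static void col2imT(const arma::fmat& colsT, int H, int W, int C,
                    int kh, int kw, int ph0, int pw0, int stride,
                    int OH, int OW, float* x) {
  for (int c = 0; c < C; ++c) {
    float* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        const float* srccol = colsT.colptr(r);
        if (stride == 1) {
          int off = ki - ph0;
          int o0 = std::max(0, -off), o1 = std::min(OH, H - off);
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow - pw0 + kj;
            if (iw < 0 || iw >= W) continue;
            const float* src = srccol + (size_t)OH * ow;
            float* dst = xc + (size_t)iw * H + off;
            for (int oh = o0; oh < o1; ++oh) dst[oh] += src[oh];
          }
        } else {
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow * stride - pw0 + kj;
            if (iw < 0 || iw >= W) continue;
            const float* src = srccol + (size_t)OH * ow;
            float* xcw = xc + (size_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              int ih = oh * stride - ph0 + ki;
              if (ih >= 0 && ih < H) xcw[ih] += src[oh];
            }
          }
        }
      }
    }
  }
}

// Variants writing into / reading from a matrix whose column stride
// (ldc) exceeds the per-sample patch count, so a batch shares one matrix.
static void im2colT_strided(const float* x, int H, int W, int C,
                            int kh, int kw, int ph0, int pw0, int stride,
                            int OH, int OW, float* base, size_t ldc) {
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        float* dstcol = base + ldc * r;
        if (stride == 1) {
          int off = ki - ph0;
          int o0 = std::max(0, -off), o1 = std::min(OH, H - off);
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow - pw0 + kj;
            float* dst = dstcol + (size_t)OH * ow;
            if (iw < 0 || iw >= W) {
              std::fill(dst, dst + OH, 0.0f);
              continue;
            }
            const float* src = xc + (size_t)iw * H + off;
            if (o0 > 0) std::fill(dst, dst + o0, 0.0f);
            if (o1 > o0) std::copy(src + o0, src + o1, dst + o0);
            if (o1 < OH) std::fill(dst + std::max(o1, 0), dst + OH, 0.0f);
          }
        } else {
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow * stride - pw0 + kj;
            float* dst = dstcol + (size_t)OH * ow;
            if (iw < 0 || iw >= W) {
              std::fill(dst, dst + OH, 0.0f);
              continue;
            }
            const float* xcw = xc + (size_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              int ih = oh * stride - ph0 + ki;
              dst[oh] = (ih >= 0 && ih < H) ? xcw[ih] : 0.0f;
            }
          }
        }
      }
    }
  }
}

static void col2imT_strided(const float* base, size_t ldc,
                            int H, int W, int C,
                            int kh, int kw, int ph0, int pw0, int stride,
                            int OH, int OW, float* x) {
  for (int c = 0; c < C; ++c) {
    float* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        const float* srccol = base + ldc * r;
        if (stride == 1) {
          int off = ki - ph0;
          int o0 = std::max(0, -off), o1 = std::min(OH, H - off);
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow - pw0 + kj;
            if (iw < 0 || iw >= W) continue;
            const float* src = srccol + (size_t)OH * ow;
            float* dst = xc + (size_t)iw * H + off;
            for (int oh = o0; oh < o1; ++oh) dst[oh] += src[oh];
          }
        } else {
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow * stride - pw0 + kj;
            if (iw < 0 || iw >= W) continue;
            const float* src = srccol + (size_t)OH * ow;
            float* xcw = xc + (size_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              int ih = oh * stride - ph0 + ki;
              if (ih >= 0 && ih < H) xcw[ih] += src[oh];
            }
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Reused scratch buffers: conv layers are called hundreds of times per
// training run and per-call multi-MB allocations dominate otherwise.
static std::vector<float>& workspace(int slot, size_t n) {
  static std::vector<float> ws[4];
  if (ws[slot].size() < n) ws[slot].resize(n);
  return ws[slot];
}

static void as_float(const NumericVector& v, std::vector<float>& out) {
  out.resize(v.size());
  const double* p = REAL(v);
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)p[i];
}

extern "C" void sgemm_(const char* ta, const char* tb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* A, const int* lda, const float* B,
                       const int* ldb, const float* beta, float* C,
                       const int* ldc);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

// act: 0 = linear, 1 = ReLU, 2 = sigmoid
static inline double activate(double v, int act) {
  if (act == 1) return v > 0 ? v : 0.0;
  if (act == 2) {
    double s = 1.0 / (1.0 + std::exp(-v));
    // clamp so downstream cross-entropy gradients never vanish entirely
    if (s < 1e-7) s = 1e-7;
    if (s > 1.0 - 1e-7) s = 1.0 - 1e-7;
    return s;
  }
  return v;
}

// Stride-1 2D convolution (cross-correlation) with explicit padding and
// fused activation. x: (H,W,C,N); w: (kh,kw,C,F); b: length F.
// Returns (OH,OW,F,N).
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           IntegerVector pads, int act) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int ph0 = pads[0], ph1 = pads[1], pw0 = pads[2], pw1 = pads[3];
  int H2 = H + ph0 + ph1, W2 = W + pw0 + pw1;
  int OH = H2 - kh + 1, OW = W2 - kw + 1;
  size_t P2 = (size_t)H2 * W2;

  // weights rearranged to kh*kw blocks of (C x F)
  std::vector<float>& wr = workspace(0, (size_t)kh * kw * C * F);
  const double* wp = REAL(w);
  for (int ki = 0; ki < kh; ++ki)
    for (int kj = 0; kj < kw; ++kj)
      for (int c = 0; c < C; ++c)
        for (int f = 0; f < F; ++f)
          wr[(size_t)(ki + kh * kj) * C * F + c + (size_t)C * f] =
            (float)wp[ki + kh * (kj + kw * ((size_t)c + (size_t)C * f))];

  std::vector<float>& xpad = workspace(1, P2 * C);
  std::vector<float>& ybuf = workspace(2, P2 * F);
  NumericVector y = alloc4(OH, OW, F, N);
  double* yp = REAL(y);
  const double* xp = REAL(x);

  for (int n = 0; n < N; ++n) {
    std::fill(xpad.begin(), xpad.begin() + P2 * C, 0.0f);
    const double* xn = xp + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int w0 = 0; w0 < W; ++w0) {
        const double* src = xn + (size_t)c * H * W + (size_t)w0 * H;
        float* dst = xpad.data() + (size_t)c * P2 + (size_t)(w0 + pw0) * H2 + ph0;
        for (int i = 0; i < H; ++i) dst[i] = (float)src[i];
      }
    std::fill(ybuf.begin(), ybuf.begin() + P2 * F, 0.0f);
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int sft = ki + H2 * kj;
        int M = (int)P2 - sft;
        sgemm('N', 'N', M, F, C, 1.0f,
              xpad.data() + sft, (int)P2,
              wr.data() + (size_t)(ki + kh * kj) * C * F, C,
              1.0f, ybuf.data(), (int)P2);
      }
    double* yn = yp + (size_t)n * OH * OW * F;
    for (int f = 0; f < F; ++f) {
      double bf = b[f];
      for (int ow = 0; ow < OW; ++ow) {
        const float* src = ybuf.data() + (size_t)f * P2 + (size_t)ow * H2;
        double* dst = yn + (size_t)f * OH * OW + (size_t)ow * OH;
        for (int oh = 0; oh < OH; ++oh)
          dst[oh] = activate(src[oh] + bf, act);
      }
    }
  }
  return y;
}

// Backward pass of cpp_conv_fwd: the incoming gradient dy is w.r.t. the
// *activated* output y (both passed in); the activation derivative is
// applied internally. Set need_dx = false for layers fed by the network
// input. dy, y: (OH,OW,F,N).
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  NumericVector y, IntegerVector pads, int act, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int OH = yd[0], OW = yd[1];
  int ph0 = pads[0], ph1 = pads[1], pw0 = pads[2], pw1 = pads[3];
  int H2 = H + ph0 + ph1, W2 = W + pw0 + pw1;
  size_t P2 = (size_t)H2 * W2;

  std::vector<float>& wr = workspace(0, (size_t)kh * kw * C * F);
  const double* wp = REAL(w);
  for (int ki = 0; ki < kh; ++ki)
    for (int kj = 0; kj < kw; ++kj)
      for (int c = 0; c < C; ++c)
        for (int f = 0; f < F; ++f)
          wr[(size_t)(ki + kh * kj) * C * F + c + (size_t)C * f] =
            (float)wp[ki + kh * (kj + kw * ((size_t)c + (size_t)C * f))];

  std::vector<float>& xpad = workspace(1, P2 * C);
  std::vector<float>& gbuf = workspace(2, P2 * F);
  std::vector<float>& dxpad = workspace(3, P2 * C);
  std::vector<float> dwr((size_t)kh * kw * C * F, 0.0f);
  std::vector<double> dbacc(F, 0.0);
  NumericVector dx = need_dx ? alloc4(H, W, C, N) : NumericVector(0);
  double* dxp = need_dx ? REAL(dx) : nullptr;
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  const double* ypp = REAL(y);

  for (int n = 0; n < N; ++n) {
    // gradient w.r.t. pre-activation, laid out on the padded grid
    std::fill(gbuf.begin(), gbuf.begin() + P2 * F, 0.0f);
    const double* dyn = dyp + (size_t)n * OH * OW * F;
    const double* yn = ypp + (size_t)n * OH * OW * F;
    for (int f = 0; f < F; ++f) {
      double acc = 0.0;
      for (int ow = 0; ow < OW; ++ow) {
        const double* g = dyn + (size_t)f * OH * OW + (size_t)ow * OH;
        const double* yv = yn + (size_t)f * OH * OW + (size_t)ow * OH;
        float* dst = gbuf.data() + (size_t)f * P2 + (size_t)ow * H2;
        if (act == 1) {
          for (int oh = 0; oh < OH; ++oh) {
            float v = yv[oh] > 0 ? (float)g[oh] : 0.0f;
            dst[oh] = v; acc += v;
          }
        } else if (act == 2) {
          for (int oh = 0; oh < OH; ++oh) {
            float v = (float)(g[oh] * yv[oh] * (1.0 - yv[oh]));
            dst[oh] = v; acc += v;
          }
        } else {
          for (int oh = 0; oh < OH; ++oh) { dst[oh] = (float)g[oh]; acc += dst[oh]; }
        }
      }
      dbacc[f] += acc;
    }
    std::fill(xpad.begin(), xpad.begin() + P2 * C, 0.0f);
    const double* xn = xp + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int w0 = 0; w0 < W; ++w0) {
        const double* src = xn + (size_t)c * H * W + (size_t)w0 * H;
        float* dst = xpad.data() + (size_t)c * P2 + (size_t)(w0 + pw0) * H2 + ph0;
        for (int i = 0; i < H; ++i) dst[i] = (float)src[i];
      }
    if (need_dx) std::fill(dxpad.begin(), dxpad.begin() + P2 * C, 0.0f);
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int sft = ki + H2 * kj;
        int M = (int)P2 - sft;
        // dWk += Xpad[s..]^T * G[0..M)
        sgemm('T', 'N', C, F, M, 1.0f,
              xpad.data() + sft, (int)P2,
              gbuf.data(), (int)P2, 1.0f,
              dwr.data() + (size_t)(ki + kh * kj) * C * F, C);
        if (need_dx)
          // dXpad[s..] += G[0..M) * Wk^T
          sgemm('N', 'T', M, C, F, 1.0f,
                gbuf.data(), (int)P2,
                wr.data() + (size_t)(ki + kh * kj) * C * F, C,
                1.0f, dxpad.data() + sft, (int)P2);
      }
    if (need_dx) {
      double* dxn = dxp + (size_t)n * H * W * C;
      for (int c = 0; c < C; ++c)
        for (int w0 = 0; w0 < W; ++w0) {
          const float* src = dxpad.data() + (size_t)c * P2 +
            (size_t)(w0 + pw0) * H2 + ph0;
          double* dst = dxn + (size_t)c * H * W + (size_t)w0 * H;
          for (int i = 0; i < H; ++i) dst[i] = src[i];
        }
    }
  }
  NumericVector dw = alloc4(kh, kw, C, F);
  double* dwp = REAL(dw);
  for (int ki = 0; ki < kh; ++ki)
    for (int kj = 0; kj < kw; ++kj)
      for (int c = 0; c < C; ++c)
        for (int f = 0; f < F; ++f)
          dwp[ki + kh * (kj + kw * ((size_t)c + (size_t)C * f))] =
            dwr[(size_t)(ki + kh * kj) * C * F + c + (size_t)C * f];
  NumericVector db(F);
  for (int f = 0; f < F; ++f) db[f] = dbacc[f];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution with fused activation; output spatial size =
// stride * input size (framework-style "same" semantics: y[s*i + a] for
// kernel offsets 0 <= a < k; requires k >= stride). x: (H,W,C,N);
// w: (kh,kw,C,F).
// [[Rcpp::export]]
NumericVector cpp_tconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int act) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int OH = H * stride, OW = W * stride;
  int Kf = kh * kw * F, Pin = H * W;

  std::vector<float> xf, wf;
  as_float(x, xf); as_float(w, wf);
  // Wr: (C x Kf), Wr(c, a + kh*(b + kw*f)) = w[a,b,c,f]
  arma::fmat Wr(C, Kf);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wr(c, ki + kh * (kj + kw * f)) =
            wf[ki + kh * (kj + kw * ((size_t)c + (size_t)C * f))];

  NumericVector y = alloc4(OH, OW, F, N);
  double* yp = REAL(y);
  std::vector<float> yf((size_t)OH * OW * F);
  arma::fmat Xn(C, Pin);

  for (int n = 0; n < N; ++n) {
    const float* xn = xf.data() + (size_t)n * Pin * C;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < Pin; ++p) Xn(c, p) = xn[p + (size_t)c * Pin];
    arma::fmat VT = Xn.t() * Wr;                   // (Pin x Kf)
    std::fill(yf.begin(), yf.end(), 0.0f);
    // scatter: y[s*i+a, s*j+b, f] += VT(i + H*j, r)
    col2imT(VT, OH, OW, F, kh, kw, 0, 0, stride, H, W, yf.data());
    double* dst = yp + (size_t)n * OH * OW * F;
    for (int f = 0; f < F; ++f) {
      double bf = b[f];
      const float* src = yf.data() + (size_t)f * OH * OW;
      double* d2 = dst + (size_t)f * OH * OW;
      for (int p = 0; p < OH * OW; ++p) d2[p] = activate(src[p] + bf, act);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   NumericVector y, int stride, int act) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int OH = yd[0], OW = yd[1];
  int Kf = kh * kw * F, Pin = H * W, Pout = OH * OW;

  std::vector<float> xf, wf;
  as_float(x, xf); as_float(w, wf);
  const double* dyp = REAL(dy);
  const double* ypp = REAL(y);
  arma::fmat Wr(C, Kf);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wr(c, ki + kh * (kj + kw * f)) =
            wf[ki + kh * (kj + kw * ((size_t)c + (size_t)C * f))];

  arma::fmat GT(Pin, Kf), Xn(C, Pin);
  arma::fmat dWr(C, Kf, arma::fill::zeros);
  arma::fvec dbacc(F, arma::fill::zeros);
  NumericVector dx = alloc4(H, W, C, N);
  double* dxp = REAL(dx);
  std::vector<float> dyf((size_t)Pout * F);

  for (int n = 0; n < N; ++n) {
    const double* dyb = dyp + (size_t)n * Pout * F;
    const double* yb = ypp + (size_t)n * Pout * F;
    for (int f = 0; f < F; ++f) {
      float* dst = dyf.data() + (size_t)f * Pout;
      const double* g = dyb + (size_t)f * Pout;
      const double* yv = yb + (size_t)f * Pout;
      float acc = 0.0f;
      if (act == 1) {
        for (int p = 0; p < Pout; ++p) {
          float v = yv[p] > 0 ? (float)g[p] : 0.0f;
          dst[p] = v; acc += v;
        }
      } else if (act == 2) {
        for (int p = 0; p < Pout; ++p) {
          float v = (float)(g[p] * yv[p] * (1.0 - yv[p]));
          dst[p] = v; acc += v;
        }
      } else {
        for (int p = 0; p < Pout; ++p) { dst[p] = (float)g[p]; acc += dst[p]; }
      }
      dbacc(f) += acc;
    }
    // GT(i + H*j, r) = dy[s*i+a, s*j+b, f]
    im2colT(dyf.data(), OH, OW, F, kh, kw, 0, 0, stride, H, W, GT);
    arma::fmat dXn = Wr * GT.t();                  // (C x Pin)
    const float* xn = xf.data() + (size_t)n * Pin * C;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < Pin; ++p) Xn(c, p) = xn[p + (size_t)c * Pin];
    dWr += Xn * GT;
    double* dst = dxp + (size_t)n * Pin * C;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < Pin; ++p) dst[p + (size_t)c * Pin] = dXn(c, p);
  }
  NumericVector dw = alloc4(kh, kw, C, F);
  double* dwp = REAL(dw);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dwp[ki + kh * (kj + kw * ((size_t)c + (size_t)C * f))] =
            dWr(c, ki + kh * (kj + kw * f));
  NumericVector db(F);
  for (int f = 0; f < F; ++f) db[f] = dbacc(f);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2-style max pooling with stride == pool size. Returns pooled values and
// 1-based linear argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int pool) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = H / pool, OW = W / pool;
  NumericVector y = alloc4(OH, OW, C, N);
  IntegerVector idx = alloc4i(OH, OW, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)(n * C + c) * H * W;
      size_t base = (size_t)(n * C + c) * H * W;
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -HUGE_VAL; size_t bi = 0;
          for (int b2 = 0; b2 < pool; ++b2)
            for (int a = 0; a < pool; ++a) {
              size_t li = (size_t)(oh * pool + a) +
                          (size_t)H * (ow * pool + b2);
              if (xc[li] > best) { best = xc[li]; bi = li; }
            }
          size_t oi = (size_t)oh + (size_t)OH * ow +
                      (size_t)OH * OW * (c + (size_t)C * n);
          yp[oi] = best;
          ip[oi] = (int)(base + bi) + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ip[i] - 1] += dyp[i];
  return dx;
}

// Bilinear resize of a (H,W) or (H,W,C) array using pixel-center sampling
// (source coordinate (i + 0.5) * H/OH - 0.5, edge-clamped). Constant inputs
// resize to the same constant.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int OH, int OW) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd.size() > 2 ? xd[2] : 1;
  NumericVector y = xd.size() > 2
    ? NumericVector(Dimension(OH, OW, C)) : NumericVector(Dimension(OH, OW));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double sh = (double)H / OH, sw = (double)W / OW;
  std::vector<int> i0(OH), i1(OH); std::vector<double> fi(OH);
  for (int i = 0; i < OH; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s); i1[i] = std::min(i0[i] + 1, H - 1);
    fi[i] = s - i0[i];
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    double* yc = yp + (size_t)c * OH * OW;
    for (int j = 0; j < OW; ++j) {
      double s = (j + 0.5) * sw - 0.5;
      if (s < 0) s = 0;
      if (s > W - 1) s = W - 1;
      int j0 = (int)std::floor(s), j1 = std::min(j0 + 1, W - 1);
      double fj = s - j0;
      for (int i = 0; i < OH; ++i) {
        double v00 = xc[i0[i] + (size_t)H * j0], v10 = xc[i1[i] + (size_t)H * j0];
        double v01 = xc[i0[i] + (size_t)H * j1], v11 = xc[i1[i] + (size_t)H * j1];
        yc[i + (size_t)OH * j] =
          (1 - fi[i]) * ((1 - fj) * v00 + fj * v01) +
          fi[i] * ((1 - fj) * v10 + fj * v11);
      }
    }
  }
  return y;
}

// Nearest-neighbour resize (value-preserving; used for masks).
// [[Rcpp::export]]
NumericVector cpp_resize_nearest(NumericVector x, int OH, int OW) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd.size() > 2 ? xd[2] : 1;
  NumericVector y = xd.size() > 2
    ? NumericVector(Dimension(OH, OW, C)) : NumericVector(Dimension(OH, OW));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    double* yc = yp + (size_t)c * OH * OW;
    for (int j = 0; j < OW; ++j) {
      int js = std::min((int)std::floor((j + 0.5) * W / OW), W - 1);
      for (int i = 0; i < OH; ++i) {
        int is = std::min((int)std::floor((i + 0.5) * H / OH), H - 1);
        yc[i + (size_t)OH * j] = xc[is + (size_t)H * js];
      }
    }
  }
  return y;
}

// Inverted dropout using R's RNG stream (same draws as stats::runif), so
// seed-reproducibility is governed by set.seed like every other source of
// randomness. Returns the scaled output and the kept-mask as a raw vector.
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericVector x, double rate) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  RawVector mask(n);
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  Rbyte* mp = RAW(mask);
  double scale = 1.0 / (1.0 - rate);
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (unif_rand() >= rate) { mp[i] = 1; yp[i] = xp[i] * scale; }
    else { mp[i] = 0; yp[i] = 0.0; }
  }
  PutRNGstate();
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector cpp_dropout_bwd(NumericVector g, RawVector mask, double rate) {
  R_xlen_t n = g.size();
  NumericVector dx(n);
  dx.attr("dim") = g.attr("dim");
  const double* gp = REAL(g);
  double* dp = REAL(dx);
  const Rbyte* mp = RAW(mask);
  double scale = 1.0 / (1.0 - rate);
  for (R_xlen_t i = 0; i < n; ++i) dp[i] = mp[i] ? gp[i] * scale : 0.0;
  return dx;
}

// Channel-axis concatenation of (H,W,C_i,N) arrays: per sample, channel
// blocks are contiguous, so this is plain block copying.
// [[Rcpp::export]]
NumericVector cpp_concat4(List arrays) {
  int K = arrays.size();
  std::vector<const double*> ps(K);
  std::vector<size_t> block(K);
  IntegerVector d0 = as<NumericVector>(arrays[0]).attr("dim");
  int H = d0[0], W = d0[1], N = d0[3];
  int Ctot = 0;
  for (int k = 0; k < K; ++k) {
    NumericVector a = arrays[k];
    IntegerVector d = a.attr("dim");
    ps[k] = REAL(a);
    block[k] = (size_t)H * W * d[2];
    Ctot += d[2];
  }
  NumericVector y = alloc4(H, W, Ctot, N);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    double* dst = yp + (size_t)n * H * W * Ctot;
    for (int k = 0; k < K; ++k) {
      std::copy(ps[k] + n * block[k], ps[k] + (n + 1) * block[k], dst);
      dst += block[k];
    }
  }
  return y;
}

// Inverse of cpp_concat4: split the gradient back into per-input blocks.
// [[Rcpp::export]]
List cpp_split4(NumericVector g, IntegerVector channels) {
  IntegerVector d = g.attr("dim");
  int H = d[0], W = d[1], N = d[3];
  int K = channels.size();
  int Ctot = d[2];
  List out(K);
  const double* gp = REAL(g);
  size_t off = 0;
  for (int k = 0; k < K; ++k) {
    NumericVector a = alloc4(H, W, channels[k], N);
    double* ap = REAL(a);
    size_t blk = (size_t)H * W * channels[k];
    for (int n = 0; n < N; ++n)
      std::copy(gp + (size_t)n * H * W * Ctot + off,
                gp + (size_t)n * H * W * Ctot + off + blk,
                ap + (size_t)n * blk);
    off += blk;
    out[k] = a;
  }
  return out;
}
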