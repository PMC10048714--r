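// Low-level tensor primitives for the convolutional backbones.
// Tensors are R numeric arrays with dim (H, W, N, C), column-major, so the
// element x[h, w, n, c] (0-based) lives at ((c * N + n) * W + w) * H + h.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline size_t idx4(int h, int w, int n, int c, int H, int W, int N) {
  return (((size_t)c * N + n) * W + w) * H + h;
}

// Unfold k x k patches into a matrix of shape (oH*oW*N) x (k*k*C).
// Row index r = oh + oH * (ow + oW * n); column index = kh + k*(kw + k*c).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  size_t R = (size_t)oH * oW * N;
  int K = k * k * C;
  NumericMatrix out((int)R, K);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * (kw + k * c);
        for (int n = 0; n < N; ++n) {
          for (int ow = 0; ow < oW; ++ow) {
            int w = ow * stride - pad + kw;
            bool wok = (w >= 0 && w < W);
            size_t obase = (size_t)col * R + ((size_t)n * oW + ow) * oH;
            for (int oh = 0; oh < oH; ++oh) {
              int h = oh * stride - pad + kh;
              double v = 0.0;
              if (wok && h >= 0 && h < H) v = px[idx4(h, w, n, c, H, W, N)];
              po[obase + oh] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Fold patch-gradients back onto the input (adjoint of im2col_cpp).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  size_t R = (size_t)oH * oW * N;
  NumericVector dx((size_t)H * W * N * C);
  const double* pc = cols.begin();
  double* pd = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * (kw + k * c);
        for (int n = 0; n < N; ++n) {
          for (int ow = 0; ow < oW; ++ow) {
            int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            size_t obase = (size_t)col * R + ((size_t)n * oW + ow) * oH;
            for (int oh = 0; oh < oH; ++oh) {
              int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              pd[idx4(h, w, n, c, H, W, N)] += pc[obase + oh];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling with padding by -Inf. Returns the pooled tensor and the
// 1-based linear index of each maximum into the input (0 when the whole
// window fell in the padding).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int N, int C,
                     int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  size_t len = (size_t)oH * oW * N * C;
  NumericVector out(len);
  IntegerVector arg(len);
  const double* px = x.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int ow = 0; ow < oW; ++ow)
        for (int oh = 0; oh < oH; ++oh) {
          double best = -DBL_MAX;
          size_t besti = 0;
          bool found = false;
          for (int kw = 0; kw < k; ++kw) {
            int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              size_t xi = idx4(h, w, n, c, H, W, N);
              if (!found || px[xi] > best) {
                best = px[xi];
                besti = xi;
                found = true;
              }
            }
          }
          // output written in (oh, ow, n, c) order
          size_t oi = idx4(oh, ow, n, c, oH, oW, N);
          out[oi] = found ? best : 0.0;
          arg[oi] = found ? (int)(besti + 1) : 0;
          ++o;
        }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["oH"] = oH, _["oW"] = oW);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              int in_len) {
  NumericVector dx(in_len);
  for (R_xlen_t i = 0; i < dout.size(); ++i) {
    int a = argmax[i];
    if (a > 0) dx[a - 1] += dout[i];
  }
  return dx;
}

// Depthwise (per-channel) k x k convolution, stride 1 supported with any
// stride for generality. Weights: array (k, k, C); bias: length C.
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int H, int W, int N, int C,
                             NumericVector wts, NumericVector bias,
                             int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)oH * oW * N * C);
  const double* px = x.begin();
  const double* pw = wts.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = pw + (size_t)c * k * k;
    for (int n = 0; n < N; ++n)
      for (int ow = 0; ow < oW; ++ow)
        for (int oh = 0; oh < oH; ++oh) {
          double acc = bias[c];
          for (int kw = 0; kw < k; ++kw) {
            int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              acc += px[idx4(h, w, n, c, H, W, N)] * wc[kh + k * kw];
            }
          }
          po[idx4(oh, ow, n, c, oH, oW, N)] = acc;
        }
  }
  return out;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector dout, NumericVector x,
                    int H, int W, int N, int C,
                    NumericVector wts, int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((size_t)H * W * N * C);
  NumericVector dw((size_t)k * k * C);
  NumericVector db(C);
  const double* px = x.begin();
  const double* pdo = dout.begin();
  const double* pw = wts.begin();
  double* pdx = dx.begin();
  double* pdw = dw.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = pw + (size_t)c * k * k;
    double* dwc = pdw + (size_t)c * k * k;
    double accb = 0.0;
    for (int n = 0; n < N; ++n)
      for (int ow = 0; ow < oW; ++ow)
        for (int oh = 0; oh < oH; ++oh) {
          double g = pdo[idx4(oh, ow, n, c, oH, oW, N)];
          accb += g;
          if (g == 0.0) continue;
          for (int kw = 0; kw < k; ++kw) {
            int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              size_t xi = idx4(h, w, n, c, H, W, N);
              pdx[xi] += g * wc[kh + k * kw];
              dwc[kh + k * kw] += g * px[xi];
            }
          }
        }
    db[c] = accb;
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
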