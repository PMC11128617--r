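#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Tensors are R arrays laid out [C, H, W, N] (channel fastest). 0-based index:
// c + C*(h + H*(w + W*n)).

// Patch matrix for GEMM-based convolution: rows are (c, kh, kw) with c
// fastest, columns are (oh, ow, n) with oh fastest, so weight(Cout, C*k*k) %*%
// im2col() is already the output tensor [Cout, oH, oW, N].
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, oH * oW * N);
  double *po = out.begin();
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const R_xlen_t col = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
        double *pc = po + col * (R_xlen_t)(C * k * k);
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride + kw - pad;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride + kh - pad;
            double *dst = pc + (R_xlen_t)C * (kh + k * kw);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double *src = px + (R_xlen_t)(h + (R_xlen_t)H * (w + (R_xlen_t)W * n)) * C;
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col (gradient w.r.t. the convolution input).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double *px = x.begin();
  const double *pc0 = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const R_xlen_t col = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
        const double *pc = pc0 + col * (R_xlen_t)(C * k * k);
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            const double *src = pc + (R_xlen_t)C * (kh + k * kw);
            double *dst = px + (R_xlen_t)(h + (R_xlen_t)H * (w + (R_xlen_t)W * n)) * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// Depthwise k x k convolution forward; weights laid out (c, kh, kw), c fastest.
// [[Rcpp::export]]
NumericVector depthwise_fw_cpp(NumericVector x, int C, int H, int W, int N,
                               NumericVector wt, int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)C * oH * oW * N);
  double *po = out.begin();
  const double *px = x.begin(), *pw = wt.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        double *dst = po + (R_xlen_t)(oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n)) * C;
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            const double *src = px + (R_xlen_t)(h + (R_xlen_t)H * (w + (R_xlen_t)W * n)) * C;
            const double *wk = pw + (R_xlen_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) dst[c] += wk[c] * src[c];
          }
        }
      }
    }
  }
  return out;
}

// Depthwise backward: gradients w.r.t. input and weights in one pass.
// [[Rcpp::export]]
List depthwise_bw_cpp(NumericVector dout, NumericVector x, int C, int H, int W,
                      int N, NumericVector wt, int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((R_xlen_t)C * H * W * N);
  NumericVector dw((R_xlen_t)C * k * k);
  double *pdx = dx.begin(), *pdw = dw.begin();
  const double *pdo = dout.begin(), *px = x.begin(), *pw = wt.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const double *g = pdo + (R_xlen_t)(oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n)) * C;
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            const R_xlen_t xoff = (R_xlen_t)(h + (R_xlen_t)H * (w + (R_xlen_t)W * n)) * C;
            const double *src = px + xoff;
            double *d = pdx + xoff;
            const double *wk = pw + (R_xlen_t)C * (kh + k * kw);
            double *dwk = pdw + (R_xlen_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) {
              d[c] += wk[c] * g[c];
              dwk[c] += src[c] * g[c];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling with argmax bookkeeping for the backward pass.
// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, int C, int H, int W, int N,
                    int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)C * oH * oW * N);
  IntegerVector arg((R_xlen_t)C * oH * oW * N);
  double *po = out.begin();
  int *pa = arg.begin();
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const R_xlen_t ooff = (R_xlen_t)(oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n)) * C;
        for (int c = 0; c < C; ++c) {
          double best = -DBL_MAX;
          R_xlen_t besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w = ow * stride + kw - pad;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = oh * stride + kh - pad;
              if (h < 0 || h >= H) continue;
              const R_xlen_t xi = c + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              if (px[xi] > best) { best = px[xi]; besti = xi; }
            }
          }
          po[ooff + c] = best;
          pa[ooff + c] = (int)besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector dout, IntegerVector argmax,
                             R_xlen_t in_len) {
  NumericVector dx(in_len);
  const double *pd = dout.begin();
  const int *pa = argmax.begin();
  double *px = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) px[pa[i]] += pd[i];
  return dx;
}
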