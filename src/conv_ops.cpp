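#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Feature maps are stored channel-first as numeric arrays with dim
// (C, H, W, B), C fastest. im2col unrolls k x k receptive fields (zero
// padding `pad`, stride `stride`) into a (C*k*k) x (oH*oW*B) matrix whose row
// index runs channel fastest, then kh, then kw -- so each (kh, kw) offset is
// one contiguous memcpy of C doubles from the source. The matching weight
// matrix is matrix(aperm(W, c(3, 1, 2, 4)), C*k*k, Cout) for a weight array
// with dim (k, k, C, Cout). Column index runs oh fastest, then ow, then
// batch, so the convolution output Wmat' * cols reshapes directly to
// (Cout, oH, oW, B).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int B,
                         int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, oH * oW * B);
  const double *px = x.begin();
  double *po = out.begin();
  long nrow = (long)C * k * k;
  for (int b = 0; b < B; ++b) {
    const double *src = px + (long)b * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        long col = (long)b * oH * oW + (long)ow * oH + oh;
        double *dst = po + col * nrow;
        int h0 = oh * stride - pad;
        int w0 = ow * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh;
            double *d = dst + ((long)kw * k + kh) * C;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
              std::memcpy(d, src + (long)C * (hi + (long)H * wi),
                          C * sizeof(double));
            } else {
              std::memset(d, 0, C * sizeof(double));
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto the (C, H, W, B) input.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int B,
                         int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector x((long)H * W * C * B);
  double *px = x.begin();
  const double *pc = cols.begin();
  long nrow = (long)C * k * k;
  for (int b = 0; b < B; ++b) {
    double *dst = px + (long)b * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        long col = (long)b * oH * oW + (long)ow * oH + oh;
        const double *src = pc + col * nrow;
        int h0 = oh * stride - pad;
        int w0 = ow * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            double *d = dst + (long)C * (hi + (long)H * wi);
            const double *s = src + ((long)kw * k + kh) * C;
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W, B);
  return x;
}

// Max pooling over k x k windows on a (C, H, W, B) array. Returns the pooled
// map plus the 1-based linear index of each selected input element, so the
// backward pass is a scatter.
// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, int C, int H, int W, int B,
                 int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector out((long)oH * oW * C * B);
  IntegerVector arg((long)oH * oW * C * B);
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = arg.begin();
  for (int b = 0; b < B; ++b) {
    const double *src = px + (long)b * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        long base = (long)b * C * oH * oW + (long)C * (oh + (long)oH * ow);
        int h0 = oh * stride - pad, w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) { po[base + c] = R_NegInf; pa[base + c] = 0; }
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            const double *s = src + (long)C * (hi + (long)H * wi);
            long idx0 = (long)b * C * H * W + (long)C * (hi + (long)H * wi);
            for (int c = 0; c < C; ++c) {
              if (s[c] > po[base + c]) {
                po[base + c] = s[c];
                pa[base + c] = (int)(idx0 + c + 1);
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, oH, oW, B);
  arg.attr("dim") = IntegerVector::create(C, oH, oW, B);
  return List::create(_["out"] = out, _["argmax"] = arg);
}
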