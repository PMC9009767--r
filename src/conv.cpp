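// Convolution kernels for the residual backbone (im2col + GEMM).
// Array layout follows R column-major order: activations are H x W x C x N,
// kernels are kh x kw x Cin x Cout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix for image n: rows index output positions
// (oh + H2*ow), columns index kernel taps (i + kh*(j + kw*c)).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int H2, int W2, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        for (int ow = 0; ow < W2; ++ow) {
          const int w_in = ow * stride + j - pad;
          const bool w_ok = (w_in >= 0 && w_in < W);
          for (int oh = 0; oh < H2; ++oh) {
            const int h_in = oh * stride + i - pad;
            double v = 0.0;
            if (w_ok && h_in >= 0 && h_in < H)
              v = x[h_in + H * (w_in + W * c)];
            M(oh + H2 * ow, col) = v;
          }
        }
      }
    }
  }
}

// Scatter-add the columns matrix back into the input gradient (col2im).
static void col2im_add(const arma::mat& M, double* dx, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int H2, int W2) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        for (int ow = 0; ow < W2; ++ow) {
          const int w_in = ow * stride + j - pad;
          if (w_in < 0 || w_in >= W) continue;
          for (int oh = 0; oh < H2; ++oh) {
            const int h_in = oh * stride + i - pad;
            if (h_in < 0 || h_in >= H) continue;
            dx[h_in + H * (w_in + W * c)] += M(oh + H2 * ow, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  const int H2 = out_size(H, kh, stride, pad);
  const int W2 = out_size(W, kw, stride, pad);
  if (H2 <= 0 || W2 <= 0) stop("kernel larger than padded input");

  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout,
                     false, true);
  NumericVector y(H2 * W2 * Cout * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);

  arma::mat M(H2 * W2, kh * kw * Cin);
  const size_t xstride = (size_t)H * W * C;
  const size_t ystride = (size_t)H2 * W2 * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstride, H, W, C, kh, kw, stride, pad, H2, W2, M);
    arma::mat Yn(y.begin() + n * ystride, H2 * W2, Cout, false, true);
    Yn = M * Wm;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int H2 = out_size(H, kh, stride, pad);
  const int W2 = out_size(W, kw, stride, pad);

  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout,
                     false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);

  arma::mat M(H2 * W2, kh * kw * Cin);
  const size_t xstride = (size_t)H * W * C;
  const size_t ystride = (size_t)H2 * W2 * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstride, H, W, C, kh, kw, stride, pad, H2, W2, M);
    const arma::mat dYn(const_cast<double*>(dy.begin()) + n * ystride,
                        H2 * W2, Cout, false, true);
    dWm += M.t() * dYn;
    arma::mat dM = dYn * Wm.t();
    col2im_add(dM, dx.begin() + n * xstride, H, W, C, kh, kw, stride, pad,
               H2, W2);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
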