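// Low-level kernels for the autograd engine: im2col/col2im lowering of
// (transposed) convolutions and pooling. Tensor layout throughout:
// (H, W, C, N) column-major R arrays, i.e. index = h + H*(w + W*(c + C*n)).
// im2col row order: kh fastest, then kw, then channel; column order:
// output row fastest, then output col, then batch element.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::mat cpp_im2col(const NumericVector& x, int H, int W, int C, int N,
                     int kh, int kw, int stride, int pad) {
  const int OH = out_size(H, kh, stride, pad);
  const int OW = out_size(W, kw, stride, pad);
  arma::mat cols(kh * kw * C, (size_t)OH * OW * N, arma::fill::zeros);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const size_t col = (size_t)oh + (size_t)OH * ow + (size_t)OH * OW * n;
        double* cp = cols.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = ow * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xc + (size_t)H * wi;
            const int base = kh * (kj + kw * c);
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              cp[base + ki] = xcol[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(const arma::mat& cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int OH = out_size(H, kh, stride, pad);
  const int OW = out_size(W, kw, stride, pad);
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const size_t col = (size_t)oh + (size_t)OH * ow + (size_t)OH * OW * n;
        const double* cp = cols.colptr(col);
        for (int c = 0; c < C; ++c) {
          double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = ow * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            double* xcol = xc + (size_t)H * wi;
            const int base = kh * (kj + kw * c);
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              xcol[hi] += cp[base + ki];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Average pooling with constant divisor k*k (padding counted).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(const NumericVector& x, int H, int W, int C,
                              int N, int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  NumericVector out((size_t)OH * OW * C * N);
  const double inv = 1.0 / (k * k);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* oc = op + (size_t)OH * OW * (c + (size_t)C * n);
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double s = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = ow * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              s += xc[hi + (size_t)H * wi];
            }
          }
          oc[oh + (size_t)OH * ow] = s * inv;
        }
    }
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(const NumericVector& gout, int H, int W, int C,
                              int N, int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  NumericVector gx((size_t)H * W * C * N);
  const double inv = 1.0 / (k * k);
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* gc = gp + (size_t)OH * OW * (c + (size_t)C * n);
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          const double g = gc[oh + (size_t)OH * ow] * inv;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = ow * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              xc[hi + (size_t)H * wi] += g;
            }
          }
        }
    }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// Max pooling; returns the pooled map and 1-based argmax positions into
// the flattened input, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& x, int H, int W, int C, int N,
                     int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  NumericVector out((size_t)OH * OW * C * N);
  IntegerVector arg((size_t)OH * OW * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      const double* xc = xp + xoff;
      const size_t ooff = (size_t)OH * OW * (c + (size_t)C * n);
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = ow * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bidx = xoff + hi + (size_t)H * wi; }
            }
          }
          op[ooff + oh + (size_t)OH * ow] = best;
          ap[ooff + oh + (size_t)OH * ow] = (int)(bidx + 1);
        }
    }
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& gout,
                              const IntegerVector& argmax, int H, int W,
                              int C, int N) {
  NumericVector gx((size_t)H * W * C * N);
  double* xp = gx.begin();
  const double* gp = gout.begin();
  const int* ap = argmax.begin();
  const size_t M = gout.size();
  for (size_t i = 0; i < M; ++i) xp[ap[i] - 1] += gp[i];
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}
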