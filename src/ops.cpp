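#include <Rcpp.h>
using namespace Rcpp;

// Activation layout used throughout the package: a feature map batch is a
// numeric matrix of shape (H*W*N) x C with row index r = h + H*(w + W*n)
// (column-major over height, width, image) and one column per channel.
// Convolution weights are flattened to (K*K*Cin) x Cout with row index
// kh + K*(kw + K*cin).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& X, int H, int W, int N,
                         int K, int stride, int pad_top, int pad_left,
                         int Hout, int Wout) {
  const int Cin = X.ncol();
  NumericMatrix out(Hout * Wout * N, K * K * Cin);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const int r = ho + Hout * (wo + Wout * n);
        for (int c = 0; c < Cin; ++c) {
          for (int kw = 0; kw < K; ++kw) {
            const int wi = wo * stride - pad_left + kw;
            const bool win = (wi >= 0 && wi < W);
            for (int kh = 0; kh < K; ++kh) {
              const int hi = ho * stride - pad_top + kh;
              const int col = kh + K * (kw + K * c);
              double v = 0.0;
              if (win && hi >= 0 && hi < H)
                v = X(hi + H * (wi + W * n), c);
              out(r, col) = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add the column matrix gradient back onto the input tensor
// (adjoint of im2col_cpp).
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& dcols, int H, int W, int N,
                         int Cin, int K, int stride, int pad_top, int pad_left,
                         int Hout, int Wout) {
  NumericMatrix dX(H * W * N, Cin);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const int r = ho + Hout * (wo + Wout * n);
        for (int c = 0; c < Cin; ++c) {
          for (int kw = 0; kw < K; ++kw) {
            const int wi = wo * stride - pad_left + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int hi = ho * stride - pad_top + kh;
              if (hi < 0 || hi >= H) continue;
              const int col = kh + K * (kw + K * c);
              dX(hi + H * (wi + W * n), c) += dcols(r, col);
            }
          }
        }
      }
    }
  }
  return dX;
}

// Depthwise KxK convolution; Wt is (K*K) x C with row index kh + K*kw.
// [[Rcpp::export]]
NumericMatrix dwconv_fwd_cpp(const NumericMatrix& X, int H, int W, int N,
                             const NumericMatrix& Wt, int K, int stride,
                             int pad_top, int pad_left, int Hout, int Wout) {
  const int C = X.ncol();
  NumericMatrix Y(Hout * Wout * N, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          double s = 0.0;
          for (int kw = 0; kw < K; ++kw) {
            const int wi = wo * stride - pad_left + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int hi = ho * stride - pad_top + kh;
              if (hi < 0 || hi >= H) continue;
              s += X(hi + H * (wi + W * n), c) * Wt(kh + K * kw, c);
            }
          }
          Y(ho + Hout * (wo + Wout * n), c) = s;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(const NumericMatrix& X, const NumericMatrix& dY,
                    int H, int W, int N, const NumericMatrix& Wt,
                    int K, int stride, int pad_top, int pad_left,
                    int Hout, int Wout) {
  const int C = X.ncol();
  NumericMatrix dX(H * W * N, C);
  NumericMatrix dW(K * K, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          const double g = dY(ho + Hout * (wo + Wout * n), c);
          if (g == 0.0) continue;
          for (int kw = 0; kw < K; ++kw) {
            const int wi = wo * stride - pad_left + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int hi = ho * stride - pad_top + kh;
              if (hi < 0 || hi >= H) continue;
              const int ri = hi + H * (wi + W * n);
              dX(ri, c) += g * Wt(kh + K * kw, c);
              dW(kh + K * kw, c) += g * X(ri, c);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dX, _["dw"] = dW);
}

static inline void src_weights(int i, double scale, int limit,
                               int& i0, int& i1, double& w1) {
  // half-pixel (align-corners-off) source coordinate
  double src = (i + 0.5) * scale - 0.5;
  double f = std::floor(src);
  w1 = src - f;
  i0 = (int)f;
  i1 = i0 + 1;
  if (i0 < 0) i0 = 0;
  if (i1 < 0) i1 = 0;
  if (i0 > limit - 1) i0 = limit - 1;
  if (i1 > limit - 1) i1 = limit - 1;
}

// Bilinear resize of every channel of every image in the batch.
// [[Rcpp::export]]
NumericMatrix bilinear_resize_cpp(const NumericMatrix& X, int H, int W, int N,
                                  int Hout, int Wout) {
  const int C = X.ncol();
  NumericMatrix Y(Hout * Wout * N, C);
  const double sh = (double)H / Hout, sw = (double)W / Wout;
  std::vector<int> h0(Hout), h1(Hout), w0(Wout), w1(Wout);
  std::vector<double> fh(Hout), fw(Wout);
  for (int i = 0; i < Hout; ++i) src_weights(i, sh, H, h0[i], h1[i], fh[i]);
  for (int j = 0; j < Wout; ++j) src_weights(j, sw, W, w0[j], w1[j], fw[j]);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const int off = H * W * n, ooff = Hout * Wout * n;
      for (int j = 0; j < Wout; ++j) {
        for (int i = 0; i < Hout; ++i) {
          const double a = X(h0[i] + H * w0[j] + off, c);
          const double b = X(h1[i] + H * w0[j] + off, c);
          const double d = X(h0[i] + H * w1[j] + off, c);
          const double e = X(h1[i] + H * w1[j] + off, c);
          const double top = a * (1 - fh[i]) + b * fh[i];
          const double bot = d * (1 - fh[i]) + e * fh[i];
          Y(i + Hout * j + ooff, c) = top * (1 - fw[j]) + bot * fw[j];
        }
      }
    }
  }
  return Y;
}

// Adjoint of bilinear_resize_cpp (scatter gradients back to the source grid).
// [[Rcpp::export]]
NumericMatrix bilinear_resize_bwd_cpp(const NumericMatrix& dY, int H, int W,
                                      int N, int Hout, int Wout) {
  const int C = dY.ncol();
  NumericMatrix dX(H * W * N, C);
  const double sh = (double)H / Hout, sw = (double)W / Wout;
  std::vector<int> h0(Hout), h1(Hout), w0(Wout), w1(Wout);
  std::vector<double> fh(Hout), fw(Wout);
  for (int i = 0; i < Hout; ++i) src_weights(i, sh, H, h0[i], h1[i], fh[i]);
  for (int j = 0; j < Wout; ++j) src_weights(j, sw, W, w0[j], w1[j], fw[j]);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const int off = H * W * n, ooff = Hout * Wout * n;
      for (int j = 0; j < Wout; ++j) {
        for (int i = 0; i < Hout; ++i) {
          const double g = dY(i + Hout * j + ooff, c);
          if (g == 0.0) continue;
          dX(h0[i] + H * w0[j] + off, c) += g * (1 - fh[i]) * (1 - fw[j]);
          dX(h1[i] + H * w0[j] + off, c) += g * fh[i] * (1 - fw[j]);
          dX(h0[i] + H * w1[j] + off, c) += g * (1 - fh[i]) * fw[j];
          dX(h1[i] + H * w1[j] + off, c) += g * fh[i] * fw[j];
        }
      }
    }
  }
  return dX;
}

// Per-row maximum and (1-based) argmax over columns.
// [[Rcpp::export]]
List rowmax_cpp(const NumericMatrix& X) {
  const int n = X.nrow(), C = X.ncol();
  NumericVector mx(n);
  IntegerVector idx(n);
  for (int r = 0; r < n; ++r) {
    double best = X(r, 0);
    int bi = 0;
    for (int c = 1; c < C; ++c) {
      if (X(r, c) > best) { best = X(r, c); bi = c; }
    }
    mx[r] = best;
    idx[r] = bi + 1;
  }
  return List::create(_["max"] = mx, _["idx"] = idx);
}

// ---- lightweight elementwise helpers (hot paths; sweep() is too slow) ----

// [[Rcpp::export]]
NumericMatrix colscale_cpp(const NumericMatrix& X, const NumericVector& v) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double s = v[c];
    for (int r = 0; r < n; ++r) Y(r, c) = X(r, c) * s;
  }
  return Y;
}

// Y = X * a[col] + b[col]
// [[Rcpp::export]]
NumericMatrix colaffine_cpp(const NumericMatrix& X, const NumericVector& a,
                            const NumericVector& b) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double s = a[c], t = b[c];
    for (int r = 0; r < n; ++r) Y(r, c) = X(r, c) * s + t;
  }
  return Y;
}

// Y(r, c) = X(r, c) * S(r / hw, c): per-image, per-channel scaling.
// [[Rcpp::export]]
NumericMatrix blockscale_cpp(const NumericMatrix& X, const NumericMatrix& S,
                             int hw) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < n; ++r) Y(r, c) = X(r, c) * S(r / hw, c);
  }
  return Y;
}

// Repeat each row of S hw times (block expansion), scaled by `scale`.
// [[Rcpp::export]]
NumericMatrix blockexpand_cpp(const NumericMatrix& S, int hw, double scale) {
  const int N = S.nrow(), C = S.ncol();
  NumericMatrix Y(N * hw, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double v = S(n, c) * scale;
      for (int k = 0; k < hw; ++k) Y(n * hw + k, c) = v;
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix relu_cpp(const NumericMatrix& X) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < n; ++r) {
      const double v = X(r, c);
      Y(r, c) = v > 0 ? v : 0.0;
    }
  return Y;
}

// G masked by positivity of Y (ReLU backward).
// [[Rcpp::export]]
NumericMatrix relu_mask_cpp(const NumericMatrix& G, const NumericMatrix& Y) {
  const int n = G.nrow(), C = G.ncol();
  NumericMatrix O(n, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < n; ++r) O(r, c) = Y(r, c) > 0 ? G(r, c) : 0.0;
  return O;
}

// Per-image column sums: (hw*N) x C -> N x C (adjoint of blockexpand).
// [[Rcpp::export]]
NumericMatrix blockcolsum_cpp(const NumericMatrix& X, int hw) {
  const int n = X.nrow(), C = X.ncol(), N = n / hw;
  NumericMatrix Y(N, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < n; ++r) Y(r / hw, c) += X(r, c);
  return Y;
}

// ---- fused batch-norm (+ optional ReLU) training kernels ----
// These avoid materializing the normalized tensor: the backward pass
// recomputes xhat from the saved pre-BN activations.

// Per-column mean and biased variance in one read pass.
// [[Rcpp::export]]
List bn_moments_cpp(const NumericMatrix& x) {
  const int n = x.nrow(), C = x.ncol();
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int r = 0; r < n; ++r) {
      const double v = x(r, c);
      s += v;
      s2 += v * v;
    }
    const double m = s / n;
    mu[c] = m;
    var[c] = s2 / n - m * m;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// a = gamma * (x - mu) * inv + beta, optionally through ReLU.
// [[Rcpp::export]]
NumericMatrix bn_act_fwd_cpp(const NumericMatrix& x, const NumericVector& mu,
                             const NumericVector& inv,
                             const NumericVector& gamma,
                             const NumericVector& beta, bool relu) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix a(n, C);
  for (int c = 0; c < C; ++c) {
    const double sc = gamma[c] * inv[c];
    const double sh = beta[c] - mu[c] * sc;
    for (int r = 0; r < n; ++r) {
      double v = x(r, c) * sc + sh;
      if (relu && v < 0) v = 0.0;
      a(r, c) = v;
    }
  }
  return a;
}

// Fused (ReLU o BN) backward: dy is the gradient at the activation output,
// x the pre-BN tensor, a the activation output (for the ReLU mask).
// [[Rcpp::export]]
List bn_act_bwd_cpp(const NumericMatrix& dy, const NumericMatrix& x,
                    const NumericMatrix& a, const NumericVector& mu,
                    const NumericVector& inv, const NumericVector& gamma,
                    bool relu) {
  const int n = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], iv = inv[c];
    double s1 = 0.0, s2 = 0.0;
    for (int r = 0; r < n; ++r) {
      double g = dy(r, c);
      if (relu && a(r, c) <= 0) g = 0.0;
      s1 += g;
      s2 += g * (x(r, c) - m) * iv;
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double c1 = s1 / n, c2 = s2 / n, sc = gamma[c] * iv;
    for (int r = 0; r < n; ++r) {
      double g = dy(r, c);
      if (relu && a(r, c) <= 0) g = 0.0;
      dx(r, c) = sc * (g - c1 - (x(r, c) - m) * iv * c2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- fused pyramid / attention / head kernels ----

// P = bilinear_resize(SRC, Hout x Wout) + L + bias[col], in one pass.
// [[Rcpp::export]]
NumericMatrix fpn_fuse_cpp(const NumericMatrix& SRC, int H, int W, int N,
                           int Hout, int Wout, const NumericMatrix& L,
                           const NumericVector& bias) {
  const int C = SRC.ncol();
  NumericMatrix Y(Hout * Wout * N, C);
  const double sh = (double)H / Hout, sw = (double)W / Wout;
  std::vector<int> h0(Hout), h1(Hout), w0(Wout), w1(Wout);
  std::vector<double> fh(Hout), fw(Wout);
  for (int i = 0; i < Hout; ++i) src_weights(i, sh, H, h0[i], h1[i], fh[i]);
  for (int j = 0; j < Wout; ++j) src_weights(j, sw, W, w0[j], w1[j], fw[j]);
  for (int c = 0; c < C; ++c) {
    const double bc = bias[c];
    for (int n = 0; n < N; ++n) {
      const int off = H * W * n, ooff = Hout * Wout * n;
      for (int j = 0; j < Wout; ++j) {
        for (int i = 0; i < Hout; ++i) {
          const double a = SRC(h0[i] + H * w0[j] + off, c);
          const double b = SRC(h1[i] + H * w0[j] + off, c);
          const double d = SRC(h0[i] + H * w1[j] + off, c);
          const double e = SRC(h1[i] + H * w1[j] + off, c);
          const double top = a * (1 - fh[i]) + b * fh[i];
          const double bot = d * (1 - fh[i]) + e * fh[i];
          const int r = i + Hout * j + ooff;
          Y(r, c) = top * (1 - fw[j]) + bot * fw[j] + L(r, c) + bc;
        }
      }
    }
  }
  return Y;
}

// dx = dy * S(r/hw, c) + G(r/hw, c) * scale (SE input gradient).
// [[Rcpp::export]]
NumericMatrix se_bwd_dx_cpp(const NumericMatrix& dy, const NumericMatrix& S,
                            const NumericMatrix& G, int hw, double scale) {
  const int n = dy.nrow(), C = dy.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < n; ++r) {
      const int b = r / hw;
      Y(r, c) = dy(r, c) * S(b, c) + G(b, c) * scale;
    }
  return Y;
}

// Per-image column sums of A*B without materializing the product.
// [[Rcpp::export]]
NumericMatrix blockcolsum_prod_cpp(const NumericMatrix& A,
                                   const NumericMatrix& B, int hw) {
  const int n = A.nrow(), C = A.ncol(), N = n / hw;
  NumericMatrix Y(N, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < n; ++r) Y(r / hw, c) += A(r, c) * B(r, c);
  return Y;
}

// BN(+ReLU) backward whose upstream gradient arrives through global
// average pooling: the effective dy is dg(r/hw, c) / hw.
// [[Rcpp::export]]
List bn_act_bwd_gap_cpp(const NumericMatrix& dg, int hw,
                        const NumericMatrix& x, const NumericMatrix& a,
                        const NumericVector& mu, const NumericVector& inv,
                        const NumericVector& gamma, bool relu) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], iv = inv[c];
    double s1 = 0.0, s2 = 0.0;
    for (int r = 0; r < n; ++r) {
      double g = dg(r / hw, c) / hw;
      if (relu && a(r, c) <= 0) g = 0.0;
      s1 += g;
      s2 += g * (x(r, c) - m) * iv;
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double c1 = s1 / n, c2 = s2 / n, sc = gamma[c] * iv;
    for (int r = 0; r < n; ++r) {
      double g = dg(r / hw, c) / hw;
      if (relu && a(r, c) <= 0) g = 0.0;
      dx(r, c) = sc * (g - c1 - (x(r, c) - m) * iv * c2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

#include <dlfcn.h>

// Pin OpenBLAS to a fixed thread count when available. The network's GEMMs
// are small and memory-bound; thread fan-out costs more than it buys.
// [[Rcpp::export]]
void set_blas_threads_cpp(int n) {
  typedef void (*setter)(int);
  void* self = dlopen(NULL, RTLD_NOW);
  if (!self) return;
  setter f = (setter)dlsym(self, "openblas_set_num_threads");
  if (f) f(n);
}

// Direct small-Cin convolution (used for the 3-channel stem): avoids
// materializing the im2col matrix.
// [[Rcpp::export]]
NumericMatrix conv_direct_fwd_cpp(const NumericMatrix& X, int H, int W, int N,
                                  const NumericMatrix& Wt, int K, int stride,
                                  int pad_top, int pad_left,
                                  int Hout, int Wout) {
  const int Cin = X.ncol(), Cout = Wt.ncol();
  NumericMatrix Y(Hout * Wout * N, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          double s = 0.0;
          for (int ci = 0; ci < Cin; ++ci) {
            for (int kw = 0; kw < K; ++kw) {
              const int wi = wo * stride - pad_left + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < K; ++kh) {
                const int hi = ho * stride - pad_top + kh;
                if (hi < 0 || hi >= H) continue;
                s += X(hi + H * (wi + W * n), ci) *
                     Wt(kh + K * (kw + K * ci), co);
              }
            }
          }
          Y(ho + Hout * (wo + Wout * n), co) = s;
        }
      }
    }
  }
  return Y;
}

// Weight gradient of the direct convolution (input gradient not needed for
// the stem).
// [[Rcpp::export]]
NumericMatrix conv_direct_dw_cpp(const NumericMatrix& X,
                                 const NumericMatrix& dY,
                                 int H, int W, int N, int K, int stride,
                                 int pad_top, int pad_left,
                                 int Hout, int Wout) {
  const int Cin = X.ncol(), Cout = dY.ncol();
  NumericMatrix dW(K * K * Cin, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          const double g = dY(ho + Hout * (wo + Wout * n), co);
          if (g == 0.0) continue;
          for (int ci = 0; ci < Cin; ++ci) {
            for (int kw = 0; kw < K; ++kw) {
              const int wi = wo * stride - pad_left + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < K; ++kh) {
                const int hi = ho * stride - pad_top + kh;
                if (hi < 0 || hi >= H) continue;
                dW(kh + K * (kw + K * ci), co) +=
                  g * X(hi + H * (wi + W * n), ci);
              }
            }
          }
        }
      }
    }
  }
  return dW;
}
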