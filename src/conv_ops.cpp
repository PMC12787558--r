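#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are S x C matrices with S = H*W*N and 0-based row index
// r = h + H*(w + W*n), i.e. rows run down each column of each image, then
// across columns, then across the batch. This matches aperm(x, c(1,2,4,3))
// of an [H, W, N, C] array in R's column-major layout.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int N,
                         int k, int stride, int pad) {
  const int C  = x.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo * N, C * k * k);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      const int wi0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int hi0 = ho * stride - pad;
        const int r = ho + Ho * (wo + Wo * n);
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wi0 + kw;
            const bool win = wi >= 0 && wi < W;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = hi0 + kh;
              double v = 0.0;
              if (win && hi >= 0 && hi < H)
                v = x(hi + H * (wi + W * n), c);
              out(r, c * k * k + kw * k + kh) = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Depthwise k x k convolution; wk is (k*k) x C with kernel index kw*k + kh.
// [[Rcpp::export]]
NumericMatrix cpp_dwconv(const NumericMatrix& x, int H, int W, int N,
                         const NumericMatrix& wk, int k, int stride, int pad) {
  const int C  = x.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo * N, C);
  const double* xp0 = x.begin();
  const double* wp0 = wk.begin();
  double* op0 = out.begin();
  const int SX = H * W * N, SO = Ho * Wo * N, KK = k * k;
  for (int c = 0; c < C; ++c) {
    const double* xp = xp0 + (R_xlen_t)SX * c;
    const double* wp = wp0 + (R_xlen_t)KK * c;
    double* op = op0 + (R_xlen_t)SO * c;
    for (int n = 0; n < N; ++n) {
      const int xoff = H * W * n;
      for (int wo = 0; wo < Wo; ++wo) {
        const int wi0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          const int hi0 = ho * stride - pad;
          double acc = 0.0;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wi0 + kw;
            if (wi < 0 || wi >= W) continue;
            const double* col = xp + xoff + H * wi;
            const double* wcol = wp + kw * k;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              acc += col[hi] * wcol[kh];
            }
          }
          op[ho + Ho * (wo + Wo * n)] = acc;
        }
      }
    }
  }
  return out;
}

// Backward pass of the depthwise convolution: gradients w.r.t. the input
// map and the per-channel kernels.
// [[Rcpp::export]]
List cpp_dwconv_bwd(const NumericMatrix& x, const NumericMatrix& dy,
                    int H, int W, int N,
                    const NumericMatrix& wk, int k, int stride, int pad) {
  const int C  = x.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix dx(H * W * N, C);
  NumericMatrix dw(k * k, C);
  const double* xp0 = x.begin();
  const double* yp0 = dy.begin();
  const double* wp0 = wk.begin();
  double* dxp0 = dx.begin();
  double* dwp0 = dw.begin();
  const int SX = H * W * N, SO = Ho * Wo * N, KK = k * k;
  for (int c = 0; c < C; ++c) {
    const double* xp = xp0 + (R_xlen_t)SX * c;
    const double* yp = yp0 + (R_xlen_t)SO * c;
    const double* wp = wp0 + (R_xlen_t)KK * c;
    double* dxp = dxp0 + (R_xlen_t)SX * c;
    double* dwp = dwp0 + (R_xlen_t)KK * c;
    for (int n = 0; n < N; ++n) {
      const int xoff = H * W * n;
      for (int wo = 0; wo < Wo; ++wo) {
        const int wi0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          const int hi0 = ho * stride - pad;
          const double g = yp[ho + Ho * (wo + Wo * n)];
          if (g == 0.0) continue;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wi0 + kw;
            if (wi < 0 || wi >= W) continue;
            const double* col = xp + xoff + H * wi;
            double* dcol = dxp + xoff + H * wi;
            const double* wcol = wp + kw * k;
            double* dwcol = dwp + kw * k;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              dwcol[kh] += g * col[hi];
              dcol[hi]  += g * wcol[kh];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---- fused elementwise kernels (hot paths of the training loop) ----
// These trade a little recomputation in the backward pass for far fewer
// large allocations: only layer outputs are materialized, never
// normalized copies or activation sidecars.

// Single-pass per-column mean and (population) variance.
// [[Rcpp::export]]
List cpp_bn_stats(const NumericMatrix& x) {
  const int S = x.nrow(), C = x.ncol();
  NumericVector m(C), v(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int r = 0; r < S; ++r) {
      const double xv = x(r, c);
      s1 += xv;
      s2 += xv * xv;
    }
    const double mc = s1 / S;
    m[c] = mc;
    double vc = s2 / S - mc * mc;
    v[c] = vc > 0 ? vc : 0;
  }
  return List::create(_["mean"] = m, _["var"] = v);
}

// y = gamma * (x - m) * inv + beta, one output allocation.
// [[Rcpp::export]]
NumericMatrix cpp_bn_apply(const NumericMatrix& x, const NumericVector& m,
                           const NumericVector& inv, const NumericVector& gamma,
                           const NumericVector& beta) {
  const int S = x.nrow(), C = x.ncol();
  NumericMatrix y(S, C);
  for (int c = 0; c < C; ++c) {
    const double mc = m[c], ic = inv[c], gc = gamma[c], bc = beta[c];
    for (int r = 0; r < S; ++r)
      y(r, c) = gc * (x(r, c) - mc) * ic + bc;
  }
  return y;
}

// Batch-norm backward, recomputing xhat from the cached layer input.
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dout, const NumericMatrix& x,
                const NumericVector& m, const NumericVector& inv,
                const NumericVector& gamma) {
  const int S = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(S, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mc = m[c], ic = inv[c];
    double sd = 0.0, sdx = 0.0;
    for (int r = 0; r < S; ++r) {
      const double d = dout(r, c);
      sd += d;
      sdx += d * (x(r, c) - mc) * ic;
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double m1 = sd / S, m2 = sdx / S, gi = gamma[c] * ic;
    for (int r = 0; r < S; ++r)
      dx(r, c) = gi * (dout(r, c) - m1 - (x(r, c) - mc) * ic * m2);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_silu(const NumericMatrix& x) {
  const int S = x.nrow(), C = x.ncol();
  NumericMatrix y(S, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < S; ++r) {
      const double xv = x(r, c);
      y(r, c) = xv / (1.0 + std::exp(-xv));
    }
  return y;
}

// SiLU backward, recomputing the logistic factor from the cached input.
// [[Rcpp::export]]
NumericMatrix cpp_silu_bwd(const NumericMatrix& x, const NumericMatrix& dout) {
  const int S = x.nrow(), C = x.ncol();
  NumericMatrix dx(S, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < S; ++r) {
      const double xv = x(r, c);
      const double sv = 1.0 / (1.0 + std::exp(-xv));
      dx(r, c) = dout(r, c) * sv * (1.0 + xv * (1.0 - sv));
    }
  return dx;
}

// Scale row r, column c of an image-blocked map by gate(image(r), c).
// [[Rcpp::export]]
NumericMatrix cpp_scale_by_gate(const NumericMatrix& x, const NumericMatrix& g,
                                int HW) {
  const int S = x.nrow(), C = x.ncol();
  NumericMatrix y(S, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < S; ++r)
      y(r, c) = x(r, c) * g(r / HW, c);
  return y;
}

// Fused batch-norm + SiLU: y = silu(gamma * (x - m) * inv + beta).
// [[Rcpp::export]]
NumericMatrix cpp_bn_silu(const NumericMatrix& x, const NumericVector& m,
                          const NumericVector& inv, const NumericVector& gamma,
                          const NumericVector& beta) {
  const int S = x.nrow(), C = x.ncol();
  NumericMatrix y(S, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double mc = m[c], ic = inv[c], gc = gamma[c], bc = beta[c];
    const double* xc = xp + (R_xlen_t)S * c;
    double* yc = yp + (R_xlen_t)S * c;
    for (int r = 0; r < S; ++r) {
      const double z = gc * (xc[r] - mc) * ic + bc;
      yc[r] = z / (1.0 + std::exp(-z));
    }
  }
  return y;
}

// Backward of the fused pair, recomputing the normalized value and the
// logistic factor from the cached layer input.
// [[Rcpp::export]]
List cpp_bn_silu_bwd(const NumericMatrix& dout, const NumericMatrix& x,
                     const NumericVector& m, const NumericVector& inv,
                     const NumericVector& gamma, const NumericVector& beta) {
  const int S = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(S, C);
  NumericVector dgamma(C), dbeta(C);
  const double* op = dout.begin();
  const double* xp = x.begin();
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double mc = m[c], ic = inv[c], gc = gamma[c], bc = beta[c];
    const double* oc = op + (R_xlen_t)S * c;
    const double* xc = xp + (R_xlen_t)S * c;
    double* dc = dp + (R_xlen_t)S * c;
    double sd = 0.0, sdx = 0.0;
    for (int r = 0; r < S; ++r) {
      const double xh = (xc[r] - mc) * ic;
      const double z = gc * xh + bc;
      const double sv = 1.0 / (1.0 + std::exp(-z));
      const double t = oc[r] * sv * (1.0 + z * (1.0 - sv));  // d(bn out)
      dc[r] = t;           // staging buffer; finished in the second pass
      sd += t;
      sdx += t * xh;
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double m1 = sd / S, m2 = sdx / S, gi = gc * ic;
    for (int r = 0; r < S; ++r) {
      const double xh = (xc[r] - mc) * ic;
      dc[r] = gi * (dc[r] - m1 - xh * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Bilinear resize of an [H, W, 3] image (column-major array).
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(const NumericVector& img, int H, int W,
                                  int ho, int wo) {
  NumericVector out(ho * wo * 3);
  out.attr("dim") = IntegerVector::create(ho, wo, 3);
  const double* ip = img.begin();
  double* op = out.begin();
  for (int ch = 0; ch < 3; ++ch) {
    const double* pl = ip + (R_xlen_t)H * W * ch;
    double* ol = op + (R_xlen_t)ho * wo * ch;
    for (int x2 = 0; x2 < wo; ++x2) {
      double sx = (x2 + 0.5) * W / wo - 0.5;
      if (sx < 0) sx = 0; if (sx > W - 1) sx = W - 1;
      const int x0 = (int)sx, x1 = x0 + 1 < W ? x0 + 1 : W - 1;
      const double fx = sx - x0;
      for (int y2 = 0; y2 < ho; ++y2) {
        double sy = (y2 + 0.5) * H / ho - 0.5;
        if (sy < 0) sy = 0; if (sy > H - 1) sy = H - 1;
        const int y0 = (int)sy, y1 = y0 + 1 < H ? y0 + 1 : H - 1;
        const double fy = sy - y0;
        const double top = pl[y0 + H * x0] * (1 - fx) + pl[y0 + H * x1] * fx;
        const double bot = pl[y1 + H * x0] * (1 - fx) + pl[y1 + H * x1] * fx;
        ol[y2 + ho * x2] = top * (1 - fy) + bot * fy;
      }
    }
  }
  return out;
}
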