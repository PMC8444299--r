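// Minimal conv-net kernels for the image branch: im2col convolution and
// 2x2 max pooling, forward and backward.  Image layout matches an R array
// of dim c(H, W, C) flattened column-major; a batch is a (H*W*C) x B matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C, int k, int pad,
                       int stride, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int ccol = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[hi + H * wi + H * W * c];
            col(ho + Ho * wo, ccol) = v;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, int H, int W, int C,
                       const arma::mat& Wt, const arma::vec& bias,
                       int k, int pad, int stride) {
  const int B = X.n_cols;
  const int F = Wt.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat Y(Ho * Wo * F, B);
  arma::mat col(Ho * Wo, k * k * C);
  for (int b = 0; b < B; ++b) {
    im2col_one(X.colptr(b), H, W, C, k, pad, stride, Ho, Wo, col);
    arma::mat yb = col * Wt;          // (Ho*Wo) x F
    yb.each_row() += bias.t();
    std::memcpy(Y.colptr(b), yb.memptr(), sizeof(double) * Ho * Wo * F);
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& X, const arma::mat& dY, int H, int W,
                  int C, const arma::mat& Wt, int k, int pad, int stride) {
  const int B = X.n_cols;
  const int F = Wt.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat dX(H * W * C, B, arma::fill::zeros);
  arma::mat dW(Wt.n_rows, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat col(Ho * Wo, k * k * C);
  for (int b = 0; b < B; ++b) {
    im2col_one(X.colptr(b), H, W, C, k, pad, stride, Ho, Wo, col);
    arma::mat dyb(const_cast<double*>(dY.colptr(b)), Ho * Wo, F, false, true);
    dW += col.t() * dyb;
    db += arma::sum(dyb, 0).t();
    arma::mat dcol = dyb * Wt.t();    // (Ho*Wo) x (k*k*C)
    double* dx = dX.colptr(b);
    for (int c = 0; c < C; ++c) {
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          int ccol = kh + k * kw + k * k * c;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              dx[hi + H * wi + H * W * c] += dcol(ho + Ho * wo, ccol);
            }
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& X, int H, int W, int C) {
  const int B = X.n_cols;
  const int Ho = H / 2, Wo = W / 2;
  arma::mat Y(Ho * Wo * C, B);
  arma::imat amax(Ho * Wo * C, B);
  for (int b = 0; b < B; ++b) {
    const double* x = X.colptr(b);
    double* y = Y.colptr(b);
    arma::sword* am = amax.colptr(b);
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int best = -1; double bv = -1e300;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              int idx = (2 * ho + dh) + H * (2 * wo + dw) + H * W * c;
              if (x[idx] > bv) { bv = x[idx]; best = idx; }
            }
          }
          int o = ho + Ho * wo + Ho * Wo * c;
          y[o] = bv; am[o] = best;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dY, const arma::imat& amax,
                          int H, int W, int C) {
  const int B = dY.n_cols;
  arma::mat dX(H * W * C, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* dy = dY.colptr(b);
    const arma::sword* am = amax.colptr(b);
    double* dx = dX.colptr(b);
    for (arma::uword i = 0; i < dY.n_rows; ++i) dx[am[i]] += dy[i];
  }
  return dX;
}
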