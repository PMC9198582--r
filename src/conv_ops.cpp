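// Convolution kernels for the autoencoder stack.
//
// Batch layout: a batch of N images is a D x N matrix, where each column is an
// image flattened exactly like an R array of dim (H, W, C):
//   flat index = h + H*w + H*W*c            (0-based)
// Kernel-weight layout: outC x K matrices with
//   k = dh + kh*dw + kh*kw*c
// pad_mode: 0 = zero padding, 1 = replication (edge clamp) padding.
//
// Convolutions use an im2row buffer of shape (P*chunk) x K, so the GEMM
// result (P*chunk) x outC lands directly in the flat image layout (pixel
// fastest, then channel) with contiguous reads and writes throughout; images
// are chunked to keep the buffer around 32 MB.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// fill rows [r0, r0+P) of the (rows x K) im2row buffer from one image
static void im2row_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int pad_mode,
                       int outH, int outW, arma::mat& cols, size_t r0) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int k = dh + kh * dw + kh * kw * c;
        double* col = cols.colptr(k) + r0;
        for (int ow = 0; ow < outW; ++ow) {
          int w = ow * stride - pad + dw;
          double* cp = col + (size_t)outH * ow;
          if (w < 0 || w >= W) {
            if (pad_mode == 0) {
              for (int oh = 0; oh < outH; ++oh) cp[oh] = 0.0;
              continue;
            }
            w = clampi(w, 0, W - 1);
          }
          const double* xw = xc + (size_t)H * w;
          for (int oh = 0; oh < outH; ++oh) {
            const int h = oh * stride - pad + dh;
            cp[oh] = (h >= 0 && h < H) ? xw[h]
              : (pad_mode == 1 ? xw[clampi(h, 0, H - 1)] : 0.0);
          }
        }
      }
    }
  }
}

static int chunk_size(int K, int P, int N) {
  const size_t budget = (size_t)4 << 20;           // 4M doubles = 32 MB
  size_t per_img = (size_t)K * P;
  int c = (int)std::max((size_t)1, budget / std::max(per_img, (size_t)1));
  return std::min(c, N);
}

// [[Rcpp::export]]
arma::mat conv2d_fwd_cpp(const arma::mat& x, const arma::mat& Wm,
                         const arma::vec& b, int H, int W, int C,
                         int kh, int kw, int stride, int pad, int pad_mode) {
  const int N = x.n_cols;
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (W + 2 * pad - kw) / stride + 1;
  const int P = outH * outW;
  const int outC = Wm.n_rows;
  const int K = Wm.n_cols;
  arma::mat out((size_t)P * outC, N);
  const int ch = chunk_size(K, P, N);
  arma::mat cols((size_t)P * ch, K);
  arma::mat Wt = Wm.t();                            // K x outC
  for (int n0 = 0; n0 < N; n0 += ch) {
    const int nc = std::min(ch, N - n0);
    for (int i = 0; i < nc; ++i)
      im2row_one(x.colptr(n0 + i), H, W, C, kh, kw, stride, pad, pad_mode,
                 outH, outW, cols, (size_t)P * i);
    arma::mat o = cols.rows(0, (size_t)P * nc - 1) * Wt;  // (P*nc) x outC
    for (int c = 0; c < outC; ++c) {
      const double bc = b[c];
      const double* oc = o.colptr(c);
      for (int i = 0; i < nc; ++i) {
        double* op = out.colptr(n0 + i) + (size_t)P * c;
        const double* src = oc + (size_t)P * i;
        for (int p = 0; p < P; ++p) op[p] = src[p] + bc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const arma::mat& gout, const arma::mat& x,
                    const arma::mat& Wm, int H, int W, int C,
                    int kh, int kw, int stride, int pad, int pad_mode,
                    bool need_wgrad) {
  const int N = x.n_cols;
  const int D = H * W * C;
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (W + 2 * pad - kw) / stride + 1;
  const int P = outH * outW;
  const int outC = Wm.n_rows;
  const int K = Wm.n_cols;

  arma::mat gx(D, N, arma::fill::zeros);
  arma::mat gW(outC, K, arma::fill::zeros);
  arma::vec gb(outC, arma::fill::zeros);
  const int ch = chunk_size(K, P, N);
  arma::mat cols((size_t)P * ch, K);
  arma::mat G((size_t)P * ch, outC);

  for (int n0 = 0; n0 < N; n0 += ch) {
    const int nc = std::min(ch, N - n0);
    for (int i = 0; i < nc; ++i)
      for (int c = 0; c < outC; ++c)
        std::memcpy(G.colptr(c) + (size_t)P * i,
                    gout.colptr(n0 + i) + (size_t)P * c,
                    sizeof(double) * P);
    arma::mat Gv = G.rows(0, (size_t)P * nc - 1);
    gb += arma::sum(Gv, 0).t();
    if (need_wgrad) {
      for (int i = 0; i < nc; ++i)
        im2row_one(x.colptr(n0 + i), H, W, C, kh, kw, stride, pad, pad_mode,
                   outH, outW, cols, (size_t)P * i);
      gW += Gv.t() * cols.rows(0, (size_t)P * nc - 1);
    }
    arma::mat grows = Gv * Wm;                     // (P*nc) x K
    for (int i = 0; i < nc; ++i) {
      double* gxp = gx.colptr(n0 + i);
      for (int c = 0; c < C; ++c) {
        double* gxc = gxp + (size_t)H * W * c;
        for (int dw = 0; dw < kw; ++dw) {
          for (int dh = 0; dh < kh; ++dh) {
            const int k = dh + kh * dw + kh * kw * c;
            const double* gp = grows.colptr(k) + (size_t)P * i;
            for (int ow = 0; ow < outW; ++ow) {
              int w = ow * stride - pad + dw;
              if (w < 0 || w >= W) {
                if (pad_mode == 0) continue;
                w = clampi(w, 0, W - 1);
              }
              double* xw = gxc + (size_t)H * w;
              const double* col = gp + (size_t)outH * ow;
              for (int oh = 0; oh < outH; ++oh) {
                const int h = oh * stride - pad + dh;
                if (h >= 0 && h < H) xw[h] += col[oh];
                else if (pad_mode == 1) xw[clampi(h, 0, H - 1)] += col[oh];
              }
            }
          }
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
}

// [[Rcpp::export]]
arma::mat avgpool2_fwd_cpp(const arma::mat& x, int H, int W, int C) {
  const int N = x.n_cols;
  const int oH = H / 2, oW = W / 2;
  arma::mat out((size_t)oH * oW * C, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.colptr(n);
    double* op = out.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * c;
      double* oc = op + (size_t)oH * oW * c;
      for (int w = 0; w < oW; ++w)
        for (int h = 0; h < oH; ++h) {
          const double* base = xc + 2 * h + (size_t)H * 2 * w;
          oc[h + (size_t)oH * w] =
            0.25 * (base[0] + base[1] + base[H] + base[H + 1]);
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat avgpool2_bwd_cpp(const arma::mat& gout, int H, int W, int C) {
  const int N = gout.n_cols;
  const int oH = H / 2, oW = W / 2;
  arma::mat gx((size_t)H * W * C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* gp = gout.colptr(n);
    double* xp = gx.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + (size_t)oH * oW * c;
      double* xc = xp + (size_t)H * W * c;
      for (int w = 0; w < oW; ++w)
        for (int h = 0; h < oH; ++h) {
          const double g = 0.25 * gc[h + (size_t)oH * w];
          double* base = xc + 2 * h + (size_t)H * 2 * w;
          base[0] = g; base[1] = g; base[H] = g; base[H + 1] = g;
        }
    }
  }
  return gx;
}

// batch-norm forward/backward helpers (per-channel stats over batch+space);
// x viewed as (HW, C, N). These avoid large R-level temporaries.

// [[Rcpp::export]]
List bn_stats_cpp(const arma::mat& x, int HW, int C) {
  const int N = x.n_cols;
  arma::vec mu(C, arma::fill::zeros), m2(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)HW * c;
      double s = 0, s2 = 0;
      for (int i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu[c] += s; m2[c] += s2;
    }
  }
  const double m = (double)HW * N;
  mu /= m; m2 /= m;
  arma::vec v = m2 - mu % mu;
  v.transform([](double val) { return val < 0 ? 0 : val; });
  return List::create(Named("mean") = mu, Named("var") = v);
}

// [[Rcpp::export]]
arma::mat bn_apply_cpp(const arma::mat& x, int HW, int C,
                       const arma::vec& mu, const arma::vec& inv_sd,
                       const arma::vec& gamma, const arma::vec& beta) {
  const int N = x.n_cols;
  arma::mat out(x.n_rows, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.colptr(n);
    double* op = out.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * inv_sd[c];
      const double b0 = beta[c] - a * mu[c];
      const double* xc = xp + (size_t)HW * c;
      double* oc = op + (size_t)HW * c;
      for (int i = 0; i < HW; ++i) oc[i] = a * xc[i] + b0;
    }
  }
  return out;
}

// [[Rcpp::export]]
List bn_bwd_cpp(const arma::mat& gout, const arma::mat& x, int HW, int C,
                const arma::vec& mu, const arma::vec& inv_sd,
                const arma::vec& gamma, bool batch_mode) {
  const int N = gout.n_cols;
  arma::vec ggamma(C, arma::fill::zeros), gbeta(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* gp = gout.colptr(n);
    const double* xp = x.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + (size_t)HW * c;
      const double* xc = xp + (size_t)HW * c;
      double sg = 0, sgx = 0;
      for (int i = 0; i < HW; ++i) {
        const double xh = (xc[i] - mu[c]) * inv_sd[c];
        sg += gc[i];
        sgx += gc[i] * xh;
      }
      gbeta[c] += sg; ggamma[c] += sgx;
    }
  }
  arma::mat gx(gout.n_rows, N);
  const double m = (double)HW * N;
  for (int n = 0; n < N; ++n) {
    const double* gp = gout.colptr(n);
    const double* xp = x.colptr(n);
    double* op = gx.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + (size_t)HW * c;
      const double* xc = xp + (size_t)HW * c;
      double* oc = op + (size_t)HW * c;
      const double s1 = batch_mode ? gbeta[c] / m : 0.0;
      const double s2 = batch_mode ? ggamma[c] / m : 0.0;
      const double gi = gamma[c] * inv_sd[c];
      for (int i = 0; i < HW; ++i) {
        const double xh = (xc[i] - mu[c]) * inv_sd[c];
        oc[i] = gi * (gc[i] - s1 - xh * s2);
      }
    }
  }
  return List::create(Named("gx") = gx, Named("ggamma") = ggamma,
                      Named("gbeta") = gbeta);
}
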