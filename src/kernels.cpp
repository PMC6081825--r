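// Compute kernels for the encoder-decoder engine and watershed post-processing.
// Tensor convention throughout: R arrays with dim (H, W, C, N), column-major,
// so element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).

#include <RcppArmadillo.h>
#include <queue>
#include <limits>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// Tensor workloads allocate many short-lived 10-100 MB buffers. With glibc
// defaults those come from mmap and are unmapped on free, so every training
// step pays page-fault costs far exceeding the arithmetic. Raising the mmap
// and trim thresholds keeps large blocks in the heap arena for reuse.
// [[Rcpp::export(name = ".cpp_tune_malloc")]]
void cpp_tune_malloc() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

using namespace Rcpp;

static inline int out_dim(int in, int k, int dil, int stride, int pad) {
  int keff = (k - 1) * dil + 1;
  return (in + 2 * pad - keff) / stride + 1;
}

// Persistent workspaces: repeated 10-100 MB allocations cause page-fault
// churn that dominates the GEMM cost, so the im2col buffers live across
// calls and only grow. Convolution runs in single precision (standard
// deep-learning practice): the double<->float conversions fold into the
// packing passes that exist anyway, and SGEMM roughly doubles throughput.
static arma::fmat& ws_cols() { static arma::fmat m; return m; }
static arma::fmat& ws_dy() { static arma::fmat m; return m; }
static arma::fmat& ws_dcols() { static arma::fmat m; return m; }

// im2col, patch-major layout: M x K with M = Ho*Wo*N rows and K = kh*kw*C
// columns, so the inner loop writes contiguous memory. Row m = ho + Ho*(wo +
// Wo*n); column k = ki + kh*(kj + kw*c). Zero padding written explicitly
// (the workspace is not cleared between calls).
static void im2col(const double* x, int H, int W, int C, int N,
                   int kh, int kw, int dh, int dw,
                   int stride, int ph, int pw, arma::fmat& cols) {
  const int Ho = out_dim(H, kh, dh, stride, ph);
  const int Wo = out_dim(W, kw, dw, stride, pw);
  const arma::uword M = (arma::uword)Ho * Wo * N;
  cols.set_size(M, (arma::uword)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        float* col = cols.colptr((arma::uword)(ki + kh * (kj + kw * c)));
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          float* dst = col + (size_t)Ho * Wo * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pw + kj * dw;
            float* d2 = dst + (size_t)Ho * wo;
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) d2[ho] = 0.0f;
              continue;
            }
            const double* xcol = xc + (size_t)H * wi;
            if (stride == 1) {
              const int hi0 = -ph + ki * dh;
              const int lo = std::min(Ho, std::max(0, -hi0));
              const int hi = std::max(lo, std::min(Ho, H - hi0));
              for (int ho = 0; ho < lo; ++ho) d2[ho] = 0.0f;
              for (int ho = lo; ho < hi; ++ho) d2[ho] = (float)xcol[ho + hi0];
              for (int ho = hi; ho < Ho; ++ho) d2[ho] = 0.0f;
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hix = ho * stride - ph + ki * dh;
                d2[ho] = (hix < 0 || hix >= H) ? 0.0f : (float)xcol[hix];
              }
            }
          }
        }
      }
    }
  }
}

// col2im: scatter-add transpose of im2col (same M x K layout), accumulating
// into a double-precision destination.
static void col2im(const arma::fmat& cols, double* x, int H, int W, int C,
                   int N, int kh, int kw, int dh, int dw,
                   int stride, int ph, int pw) {
  const int Ho = out_dim(H, kh, dh, stride, ph);
  const int Wo = out_dim(W, kw, dw, stride, pw);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const float* col = cols.colptr((arma::uword)(ki + kh * (kj + kw * c)));
        for (int n = 0; n < N; ++n) {
          double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          const float* src = col + (size_t)Ho * Wo * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pw + kj * dw;
            if (wi < 0 || wi >= W) continue;
            double* xcol = xc + (size_t)H * wi;
            const float* s2 = src + (size_t)Ho * wo;
            if (stride == 1) {
              const int hi0 = -ph + ki * dh;
              const int lo = std::max(0, -hi0);
              const int hi = std::min(Ho, H - hi0);
              for (int ho = lo; ho < hi; ++ho) xcol[ho + hi0] += s2[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hix = ho * stride - ph + ki * dh;
                if (hix < 0 || hix >= H) continue;
                xcol[hix] += s2[ho];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix Wt, NumericVector b,
                           IntegerVector xdim, int kh, int kw, int dh, int dw,
                           int stride, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int O = Wt.nrow();
  const int Ho = out_dim(H, kh, dh, stride, ph);
  const int Wo = out_dim(W, kw, dw, stride, pw);
  arma::fmat& cols = ws_cols();
  im2col(x.begin(), H, W, C, N, kh, kw, dh, dw, stride, ph, pw, cols);
  arma::mat Wd(Wt.begin(), O, Wt.ncol(), false);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat Y = cols * Wm.t();                  // M x O, M = Ho*Wo*N
  NumericVector out((R_xlen_t)Ho * Wo * O * N);
  double* op = out.begin();
  const double* bp = b.begin();
  const size_t P = (size_t)Ho * Wo;
  for (int o = 0; o < O; ++o) {
    const float* src = Y.colptr(o);
    for (int n = 0; n < N; ++n) {
      double* dst = op + P * (o + (size_t)O * n);
      const float* s2 = src + P * n;
      const double bo = bp[o];
      for (size_t m = 0; m < P; ++m) dst[m] = (double)s2[m] + bo;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, NumericVector dy, NumericMatrix Wt,
                  IntegerVector xdim, int kh, int kw, int dh, int dw,
                  int stride, int ph, int pw, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int O = Wt.nrow();
  const int Ho = out_dim(H, kh, dh, stride, ph);
  const int Wo = out_dim(W, kw, dw, stride, pw);
  const size_t P = (size_t)Ho * Wo;
  // reshape dy (Ho,Wo,O,N) into M x O and compute db along the way
  arma::fmat& dY = ws_dy();
  dY.set_size((arma::uword)P * N, O);
  NumericVector db(O);
  const double* dp = dy.begin();
  for (int o = 0; o < O; ++o) {
    float* dst = dY.colptr(o);
    double acc = 0;
    for (int n = 0; n < N; ++n) {
      const double* src = dp + P * (o + (size_t)O * n);
      float* d2 = dst + P * n;
      for (size_t m = 0; m < P; ++m) { d2[m] = (float)src[m]; acc += src[m]; }
    }
    db[o] = acc;
  }
  arma::fmat& cols = ws_cols();
  im2col(x.begin(), H, W, C, N, kh, kw, dh, dw, stride, ph, pw, cols);
  arma::mat Wd(Wt.begin(), O, Wt.ncol(), false);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat dWf = dY.t() * cols;                // O x K
  NumericMatrix dW(O, Wt.ncol());
  std::copy(dWf.begin(), dWf.end(), dW.begin());
  if (!need_dx)
    return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = R_NilValue);
  arma::fmat& dcols = ws_dcols();
  dcols.set_size(dY.n_rows, Wm.n_cols);
  dcols = dY * Wm;                               // M x K
  NumericVector dx((R_xlen_t)H * W * C * N);     // zero-initialised
  dx.attr("dim") = xdim;
  col2im(dcols, dx.begin(), H, W, C, N, kh, kw, dh, dw, stride, ph, pw);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Fused ReLU: forward returns y = max(x, 0); backward masks dy by y > 0.
// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* dp = dy.begin();
  const double* yp = y.begin();
  double* xp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] = yp[i] > 0 ? dp[i] : 0.0;
  return dx;
}

// Inverted dropout using R's RNG (deterministic under set.seed).
// Returns y and the scaled keep-mask needed for backward.
// [[Rcpp::export(name = ".cpp_dropout_fwd")]]
List cpp_dropout_fwd(NumericVector x, double rate) {
  const R_xlen_t n = x.size();
  NumericVector y(n), mask(n);
  y.attr("dim") = x.attr("dim");
  mask.attr("dim") = x.attr("dim");
  const double scale = 1.0 / (1.0 - rate);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* mp = mask.begin();
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double keep = (unif_rand() >= rate) ? scale : 0.0;
    mp[i] = keep;
    yp[i] = xp[i] * keep;
  }
  PutRNGstate();
  return List::create(_["y"] = y, _["mask"] = mask);
}

// Batch-norm helpers: single-pass channel statistics and normalisation over
// an (H, W, C, N) array (memory-bound; kept out of R to avoid broadcast
// copies).

// [[Rcpp::export(name = ".cpp_bn_stats")]]
List cpp_bn_stats(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t P = (size_t)H * W;
  std::vector<double> s(C, 0.0), s2(C, 0.0);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pl = xp + P * (c + (size_t)C * n);
      double a = 0, b = 0;
      for (size_t m = 0; m < P; ++m) { a += pl[m]; b += pl[m] * pl[m]; }
      s[c] += a; s2[c] += b;
    }
  const double M = (double)P * N;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = s[c] / M;
    var[c] = std::max(s2[c] / M - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// y = (x - mu[c]) * ivar[c] * gamma[c] + beta[c]; also returns xhat.
// [[Rcpp::export(name = ".cpp_bn_apply")]]
List cpp_bn_apply(NumericVector x, IntegerVector xdim, NumericVector mu,
                  NumericVector ivar, NumericVector gamma, NumericVector beta) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t P = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xdim; xhat.attr("dim") = xdim;
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = P * (c + (size_t)C * n);
      const double m = mu[c], iv = ivar[c], g = gamma[c], b = beta[c];
      for (size_t k = 0; k < P; ++k) {
        const double h = (xp[off + k] - m) * iv;
        hp[off + k] = h;
        yp[off + k] = h * g + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// channel sums of dy and dy*xhat in one pass
// [[Rcpp::export(name = ".cpp_bn_sums")]]
List cpp_bn_sums(NumericVector dy, NumericVector xhat, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t P = (size_t)H * W;
  NumericVector s1(C), s2(C);
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = P * (c + (size_t)C * n);
      double a = 0, b = 0;
      for (size_t k = 0; k < P; ++k) {
        a += dp[off + k];
        b += dp[off + k] * hp[off + k];
      }
      s1[c] += a; s2[c] += b;
    }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// dx = (gamma[c]*ivar[c]/M) * (M*dy - s1[c] - xhat*s2[c])   (training mode)
// [[Rcpp::export(name = ".cpp_bn_bwd_dx")]]
NumericVector cpp_bn_bwd_dx(NumericVector dy, NumericVector xhat,
                            IntegerVector xdim, NumericVector ivar,
                            NumericVector gamma, NumericVector s1,
                            NumericVector s2, bool train) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t P = (size_t)H * W;
  const double M = (double)P * N;
  NumericVector dx(dy.size());
  dx.attr("dim") = xdim;
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = P * (c + (size_t)C * n);
      if (train) {
        const double a = gamma[c] * ivar[c] / M;
        for (size_t k = 0; k < P; ++k)
          xp[off + k] = a * (M * dp[off + k] - s1[c] - hp[off + k] * s2[c]);
      } else {
        const double a = gamma[c] * ivar[c];
        for (size_t k = 0; k < P; ++k) xp[off + k] = a * dp[off + k];
      }
    }
  return dx;
}

// 2x2 stride-2 max pooling with argmax spatial indices (1-based h + H*(w)).
// [[Rcpp::export(name = ".cpp_maxpool")]]
List cpp_maxpool(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* plane = xp + cn * H * W;
    double* yo = yp + cn * Ho * Wo;
    int* io = ip + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int best = 2 * ho + H * (2 * wo);
        double bv = plane[best];
        const int cand[3] = {2 * ho + 1 + H * (2 * wo), 2 * ho + H * (2 * wo + 1),
                             2 * ho + 1 + H * (2 * wo + 1)};
        for (int t = 0; t < 3; ++t)
          if (plane[cand[t]] > bv) { bv = plane[cand[t]]; best = cand[t]; }
        yo[ho + (size_t)Ho * wo] = bv;
        io[ho + (size_t)Ho * wo] = best;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  double* xp = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    double* plane = xp + cn * H * W;
    const double* dyo = dp + cn * Ho * Wo;
    const int* io = ip + cn * Ho * Wo;
    for (size_t m = 0; m < (size_t)Ho * Wo; ++m) plane[io[m]] += dyo[m];
  }
  return dx;
}

// Max unpooling: scatter y into a zero (2H, 2W) grid at the stored argmax.
// [[Rcpp::export(name = ".cpp_maxunpool")]]
NumericVector cpp_maxunpool(NumericVector y, IntegerVector idx, IntegerVector outdim) {
  const int H = outdim[0], W = outdim[1], C = outdim[2], N = outdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector x((R_xlen_t)H * W * C * N);
  x.attr("dim") = outdim;
  const double* yp = y.begin();
  const int* ip = idx.begin();
  double* xp = x.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    double* plane = xp + cn * H * W;
    const double* yo = yp + cn * Ho * Wo;
    const int* io = ip + cn * Ho * Wo;
    for (size_t m = 0; m < (size_t)Ho * Wo; ++m) plane[io[m]] = yo[m];
  }
  return x;
}

// [[Rcpp::export(name = ".cpp_maxunpool_bwd")]]
NumericVector cpp_maxunpool_bwd(NumericVector dx, IntegerVector idx, IntegerVector indim) {
  const int Ho = indim[0], Wo = indim[1], C = indim[2], N = indim[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector dy((R_xlen_t)Ho * Wo * C * N);
  dy.attr("dim") = indim;
  const double* dp = dx.begin();
  const int* ip = idx.begin();
  double* yp = dy.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* plane = dp + cn * H * W;
    double* yo = yp + cn * Ho * Wo;
    const int* io = ip + cn * Ho * Wo;
    for (size_t m = 0; m < (size_t)Ho * Wo; ++m) yo[m] = plane[io[m]];
  }
  return dy;
}

// Fused block tail: y = dropout(relu(bn(x) + skip)). One pass forward, one
// pass backward, instead of four separate ops each allocating intermediates.
// s (the pre-ReLU sum) is cached for backward; xhat is recomputed from x.
// [[Rcpp::export(name = ".cpp_btail_fwd")]]
List cpp_btail_fwd(NumericVector x, IntegerVector xdim,
                   Nullable<NumericVector> skip, NumericVector mu,
                   NumericVector ivar, NumericVector gamma, NumericVector beta,
                   double rate, bool use_relu) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t P = (size_t)H * W;
  const R_xlen_t n = x.size();
  NumericVector y(n), s(n);
  y.attr("dim") = xdim; s.attr("dim") = xdim;
  const double* xp = x.begin();
  const double* sk = skip.isNotNull() ? NumericVector(skip).begin() : nullptr;
  double* yp = y.begin();
  double* sp = s.begin();
  NumericVector mask;
  double* mp = nullptr;
  if (rate > 0) {
    mask = NumericVector(n);
    mask.attr("dim") = xdim;
    mp = mask.begin();
    GetRNGstate();
  }
  const double scale = rate > 0 ? 1.0 / (1.0 - rate) : 1.0;
  for (int nn = 0; nn < N; ++nn)
    for (int c = 0; c < C; ++c) {
      const size_t off = P * (c + (size_t)C * nn);
      const double m = mu[c], iv = ivar[c], g = gamma[c], b = beta[c];
      for (size_t k = 0; k < P; ++k) {
        double v = (xp[off + k] - m) * iv * g + b;
        if (sk) v += sk[off + k];
        sp[off + k] = v;
        if (use_relu && v < 0) v = 0;
        if (mp) {
          const double keep = (unif_rand() >= rate) ? scale : 0.0;
          mp[off + k] = keep;
          v *= keep;
        }
        yp[off + k] = v;
      }
    }
  if (rate > 0) PutRNGstate();
  return List::create(_["y"] = y, _["s"] = s,
                      _["mask"] = (rate > 0 ? (SEXP)mask : R_NilValue));
}

// [[Rcpp::export(name = ".cpp_btail_bwd")]]
List cpp_btail_bwd(NumericVector dy, NumericVector s, NumericVector x,
                   IntegerVector xdim, NumericVector mu, NumericVector ivar,
                   NumericVector gamma, Nullable<NumericVector> mask,
                   bool use_relu, bool has_skip, bool train) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t P = (size_t)H * W;
  const double M = (double)P * N;
  const R_xlen_t n = dy.size();
  // g = dy through dropout and relu; this is also the skip gradient
  NumericVector gv(n);
  gv.attr("dim") = xdim;
  const double* dp = dy.begin();
  const double* sp = s.begin();
  const double* mp = mask.isNotNull() ? NumericVector(mask).begin() : nullptr;
  double* gp = gv.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = mp ? dp[i] * mp[i] : dp[i];
    if (use_relu && sp[i] <= 0) v = 0;
    gp[i] = v;
  }
  // channel sums against xhat (recomputed from x)
  NumericVector s1(C), s2(C);
  const double* xp = x.begin();
  for (int nn = 0; nn < N; ++nn)
    for (int c = 0; c < C; ++c) {
      const size_t off = P * (c + (size_t)C * nn);
      const double m = mu[c], iv = ivar[c];
      double a = 0, b = 0;
      for (size_t k = 0; k < P; ++k) {
        a += gp[off + k];
        b += gp[off + k] * (xp[off + k] - m) * iv;
      }
      s1[c] += a; s2[c] += b;
    }
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* xo = dx.begin();
  for (int nn = 0; nn < N; ++nn)
    for (int c = 0; c < C; ++c) {
      const size_t off = P * (c + (size_t)C * nn);
      const double m = mu[c], iv = ivar[c];
      if (train) {
        const double a = gamma[c] * iv / M;
        for (size_t k = 0; k < P; ++k)
          xo[off + k] = a * (M * gp[off + k] - s1[c] -
                             (xp[off + k] - m) * iv * s2[c]);
      } else {
        const double a = gamma[c] * iv;
        for (size_t k = 0; k < P; ++k) xo[off + k] = a * gp[off + k];
      }
    }
  return List::create(_["dx"] = dx,
                      _["dskip"] = (has_skip ? (SEXP)gv : R_NilValue),
                      _["dgamma"] = s2, _["dbeta"] = s1);
}

// Exact Euclidean distance transform (Felzenszwalb-Huttenlocher), distance of
// foreground pixels to the nearest background pixel. Returns distances (not squared).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericMatrix cpp_edt(LogicalMatrix fg) {
  const int H = fg.nrow(), W = fg.ncol();
  const double INF = 1e18;
  NumericMatrix d2(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = fg(i, j) ? INF : 0.0;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) d2(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d2(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) d2(i, j) = d[j];
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) d2(i, j) = std::sqrt(d2(i, j));
  return d2;
}

// Grayscale morphological reconstruction by dilation (8-connectivity),
// raster/anti-raster sweeps until stable. marker <= mask required.
// [[Rcpp::export(name = ".cpp_reconstruct")]]
NumericMatrix cpp_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  const int H = marker.nrow(), W = marker.ncol();
  NumericMatrix J = clone(marker);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double m = J(i, j);
        if (i > 0) m = std::max(m, J(i - 1, j));
        if (j > 0) m = std::max(m, J(i, j - 1));
        if (i > 0 && j > 0) m = std::max(m, J(i - 1, j - 1));
        if (i < H - 1 && j > 0) m = std::max(m, J(i + 1, j - 1));
        m = std::min(m, mask(i, j));
        if (m > J(i, j)) { J(i, j) = m; changed = true; }
      }
    for (int j = W - 1; j >= 0; --j)
      for (int i = H - 1; i >= 0; --i) {
        double m = J(i, j);
        if (i < H - 1) m = std::max(m, J(i + 1, j));
        if (j < W - 1) m = std::max(m, J(i, j + 1));
        if (i < H - 1 && j < W - 1) m = std::max(m, J(i + 1, j + 1));
        if (i > 0 && j < W - 1) m = std::max(m, J(i - 1, j + 1));
        m = std::min(m, mask(i, j));
        if (m > J(i, j)) { J(i, j) = m; changed = true; }
      }
  }
  return J;
}

// Connected-component labelling of a binary mask, 4- or 8-connectivity.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(LogicalMatrix fg, int connectivity) {
  const int H = fg.nrow(), W = fg.ncol();
  IntegerMatrix lab(H, W);
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!fg(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int t = 0; t < nn; ++t) {
          int qi = pi + dx8[t], qj = pj + dy8[t];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (fg(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + H * qj);
          }
        }
      }
    }
  return lab;
}

// Marker-controlled watershed by priority flooding on `height` (typically the
// distance transform; flooding proceeds from high to low), restricted to fg.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(NumericMatrix height, IntegerMatrix markers, LogicalMatrix fg) {
  const int H = height.nrow(), W = height.ncol();
  IntegerMatrix lab = clone(markers);
  typedef std::pair<double, long> Item;     // (-height for max-first, insertion order)
  struct Cmp {
    bool operator()(const std::pair<Item, int>& a, const std::pair<Item, int>& b) const {
      if (a.first.first != b.first.first) return a.first.first > b.first.first;
      return a.first.second > b.first.second;     // FIFO tie-break
    }
  };
  std::priority_queue<std::pair<Item, int>, std::vector<std::pair<Item, int> >, Cmp> pq;
  long counter = 0;
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0 && fg(i, j))
        pq.push(std::make_pair(Item(-height(i, j), counter++), i + H * j));
  while (!pq.empty()) {
    int p = pq.top().second; pq.pop();
    int pi = p % H, pj = p / H;
    int lp = lab(pi, pj);
    for (int t = 0; t < 8; ++t) {
      int qi = pi + dx8[t], qj = pj + dy8[t];
      if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
      if (!fg(qi, qj) || lab(qi, qj) != 0) continue;
      lab(qi, qj) = lp;
      pq.push(std::make_pair(Item(-height(qi, qj), counter++), qi + H * qj));
    }
  }
  return lab;
}
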