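// Low-level tensor kernels for the segmentation network.
//
// Layout convention: feature tensors are dense arrays with dim
// (H, W, C, N), column-major, so the (H, W) plane of one channel of one
// sample is a contiguous block of H*W values.
//
// Two precisions share one templated implementation:
//   * double tensors are ordinary numeric arrays (used by the exact
//     gradient tests);
//   * single-precision tensors are integer arrays whose 32-bit elements
//     hold float bits (class "dcnet_ft32" on the R side).  R never does
//     arithmetic on them directly -- every operation goes through these
//     kernels.  Training runs in single precision because the kernels are
//     memory-bandwidth bound; master weights, batch-norm statistics and
//     all parameter gradients stay in double.
//
// Several backward kernels accumulate gradients *in place* into a caller
// supplied buffer (needed for dense-block concatenation bookkeeping).  All
// such buffers are allocated privately by the R callers and never aliased.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline bool is_f32(SEXP x) { return TYPEOF(x) == INTSXP; }

static IntegerVector dims4(SEXP x) {
  SEXP d = Rf_getAttrib(x, R_DimSymbol);
  if (Rf_isNull(d) || Rf_length(d) != 4)
    stop("expected a 4-d (H, W, C, N) tensor");
  return IntegerVector(d);
}

template <typename T> T *data_ptr(SEXP x);
template <> double *data_ptr<double>(SEXP x) { return REAL(x); }
template <> float *data_ptr<float>(SEXP x) {
  return reinterpret_cast<float *>(INTEGER(x));
}

template <typename T> SEXP alloc_tensor(int H, int W, int C, int N);
template <> SEXP alloc_tensor<double>(int H, int W, int C, int N) {
  NumericVector out(static_cast<R_xlen_t>(H) * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}
template <> SEXP alloc_tensor<float>(int H, int W, int C, int N) {
  IntegerVector out(static_cast<R_xlen_t>(H) * W * C * N);  // zero bits = 0.0f
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  out.attr("class") = CharacterVector::create("dcnet_ft32");
  return out;
}

// Uninitialized variant for outputs that are fully overwritten.
template <typename T> SEXP alloc_tensor_raw(int H, int W, int C, int N);
template <> SEXP alloc_tensor_raw<double>(int H, int W, int C, int N) {
  SEXP out = Rf_allocVector(REALSXP, static_cast<R_xlen_t>(H) * W * C * N);
  PROTECT(out);
  Rf_setAttrib(out, R_DimSymbol, IntegerVector::create(H, W, C, N));
  UNPROTECT(1);
  return out;
}
template <> SEXP alloc_tensor_raw<float>(int H, int W, int C, int N) {
  SEXP out = Rf_allocVector(INTSXP, static_cast<R_xlen_t>(H) * W * C * N);
  PROTECT(out);
  Rf_setAttrib(out, R_DimSymbol, IntegerVector::create(H, W, C, N));
  Rf_setAttrib(out, R_ClassSymbol, CharacterVector::create("dcnet_ft32"));
  UNPROTECT(1);
  return out;
}

// Convert an R double parameter array to the working precision.
template <typename T>
static std::vector<T> cast_par(const NumericVector &v) {
  std::vector<T> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = static_cast<T>(v[i]);
  return out;
}

// ---- precision conversion (exported) --------------------------------------

// [[Rcpp::export]]
SEXP cpp_to_f32(SEXP x) {
  if (is_f32(x)) return x;
  IntegerVector d = dims4(x);
  SEXP y = PROTECT(alloc_tensor_raw<float>(d[0], d[1], d[2], d[3]));
  const double *p = REAL(x);
  float *q = data_ptr<float>(y);
  const R_xlen_t n = Rf_xlength(x);
  for (R_xlen_t i = 0; i < n; ++i) q[i] = static_cast<float>(p[i]);
  UNPROTECT(1);
  return y;
}

// [[Rcpp::export]]
SEXP cpp_to_f64(SEXP x) {
  if (!is_f32(x)) return x;
  IntegerVector d = dims4(x);
  SEXP y = PROTECT(alloc_tensor_raw<double>(d[0], d[1], d[2], d[3]));
  const float *p = data_ptr<float>(x);
  double *q = REAL(y);
  const R_xlen_t n = Rf_xlength(x);
  for (R_xlen_t i = 0; i < n; ++i) q[i] = static_cast<double>(p[i]);
  UNPROTECT(1);
  return y;
}

// ---- convolution ----------------------------------------------------------

// Direct 3x3 convolution (no im2col): the working set of one output
// column -- three input columns per channel plus the output accumulators --
// stays cache resident.  Arbitrary dilation, zero "same" padding.
template <typename T>
static void conv3x3_fwd_sample(const T *xn, int H, int W, int cin, int cout,
                               int dil, const T *wf, const T *bias, T *yn,
                               std::vector<T> &acc) {
  const int pad = dil;
  acc.assign(static_cast<size_t>(cout) * H, T(0));
  for (int w = 0; w < W; ++w) {
    if (bias)
      for (int co = 0; co < cout; ++co)
        std::fill(acc.begin() + static_cast<size_t>(co) * H,
                  acc.begin() + static_cast<size_t>(co) * H + H, bias[co]);
    else
      std::fill(acc.begin(), acc.end(), T(0));
    for (int dw = 0; dw < 3; ++dw) {
      const int iw = w + dil * dw - pad;
      if (iw < 0 || iw >= W) continue;
      for (int ci = 0; ci < cin; ++ci) {
        const T *xc = xn + H * (static_cast<size_t>(ci) * W + iw);
        for (int dh = 0; dh < 3; ++dh) {
          const int oh = dil * dh - pad;  // ih = h + oh
          const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
          if (h1 <= h0) continue;
          const T *__restrict xr = xc + oh;
          const T *wp = wf + dh + 3 * (dw + 3 * ci);
          for (int co = 0; co < cout; ++co) {
            const T wv = wp[static_cast<size_t>(co) * 9 * cin];
            T *__restrict ac = acc.data() + static_cast<size_t>(co) * H;
            for (int h = h0; h < h1; ++h) ac[h] += wv * xr[h];
          }
        }
      }
    }
    for (int co = 0; co < cout; ++co)
      std::copy(acc.begin() + static_cast<size_t>(co) * H,
                acc.begin() + static_cast<size_t>(co) * H + H,
                yn + H * (static_cast<size_t>(co) * W + w));
  }
}

// Backward companion: accumulates dx (into the first cin channels of a
// buffer whose per-sample slab is dstride channels) plus dw and db (both
// in double, independent of the working precision).
template <typename T>
static void conv3x3_bwd_sample(const T *xn, const T *dyn, int H, int W,
                               int cin, int cout, int dil, const T *wf,
                               T *dxn, double *dwf, double *db) {
  const int pad = dil;
  for (int w = 0; w < W; ++w) {
    for (int co = 0; co < cout; ++co) {
      const T *__restrict dyc = dyn + H * (static_cast<size_t>(co) * W + w);
      if (db) {
        T s = T(0);
        for (int h = 0; h < H; ++h) s += dyc[h];
        db[co] += static_cast<double>(s);
      }
      for (int dw = 0; dw < 3; ++dw) {
        const int iw = w + dil * dw - pad;
        if (iw < 0 || iw >= W) continue;
        for (int ci = 0; ci < cin; ++ci) {
          const T *xc = xn + H * (static_cast<size_t>(ci) * W + iw);
          T *dxc = dxn ? dxn + H * (static_cast<size_t>(ci) * W + iw)
                       : nullptr;
          for (int dh = 0; dh < 3; ++dh) {
            const int oh = dil * dh - pad;
            const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
            if (h1 <= h0) continue;
            const size_t wi =
              dh + 3 * (dw + 3 * (ci + static_cast<size_t>(cin) * co));
            const T wv = wf[wi];
            T s = T(0);
            const T *__restrict xs = xc + oh;
            if (dxc) {
              T *__restrict ds = dxc + oh;
              for (int h = h0; h < h1; ++h) {
                const T g = dyc[h];
                s += g * xs[h];
                ds[h] += wv * g;
              }
            } else {
              for (int h = h0; h < h1; ++h) s += dyc[h] * xs[h];
            }
            dwf[wi] += static_cast<double>(s);
          }
        }
      }
    }
  }
}

// Generic im2col fallback for kernel shapes other than 1x1 and 3x3.
template <typename T>
static void im2col(const T *xn, int H, int W, int cin, int kh, int kw,
                   int dil, arma::Mat<T> &col) {
  const int pad_h = dil * (kh - 1) / 2, pad_w = dil * (kw - 1) / 2;
  const int HW = H * W;
  for (int ci = 0; ci < cin; ++ci) {
    const T *xc = xn + static_cast<size_t>(ci) * HW;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        T *dst = col.colptr(r);
        const int oh = dil * dh - pad_h;
        const int ow = dil * dw - pad_w;
        const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        for (int w = 0; w < W; ++w) {
          T *seg = dst + static_cast<size_t>(w) * H;
          const int iw = w + ow;
          if (iw < 0 || iw >= W || h1 <= h0) {
            std::fill(seg, seg + H, T(0));
            continue;
          }
          if (h0 > 0) std::fill(seg, seg + h0, T(0));
          const T *src = xc + static_cast<size_t>(iw) * H + (h0 + oh);
          std::copy(src, src + (h1 - h0), seg + h0);
          if (h1 < H) std::fill(seg + h1, seg + H, T(0));
        }
      }
    }
  }
}

template <typename T>
static void col2im_acc(const arma::Mat<T> &col, int H, int W, int cin,
                       int kh, int kw, int dil, T *dxn) {
  const int pad_h = dil * (kh - 1) / 2, pad_w = dil * (kw - 1) / 2;
  const int HW = H * W;
  for (int ci = 0; ci < cin; ++ci) {
    T *xc = dxn + static_cast<size_t>(ci) * HW;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        const T *src0 = col.colptr(r);
        const int oh = dil * dh - pad_h;
        const int ow = dil * dw - pad_w;
        const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          const int iw = w + ow;
          if (iw < 0 || iw >= W) continue;
          const T *seg = src0 + static_cast<size_t>(w) * H + h0;
          T *dst = xc + static_cast<size_t>(iw) * H + (h0 + oh);
          for (int h = 0; h < h1 - h0; ++h) dst[h] += seg[h];
        }
      }
    }
  }
}

template <typename T>
static SEXP conv_fwd_t(SEXP xs, const NumericVector &w,
                       const NumericVector &bias, int dil) {
  IntegerVector xd = dims4(xs);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if (cin != C) stop("conv: input has %d channels, weight expects %d", C, cin);
  const int HW = H * W, R = kh * kw * cin;
  const T *x = data_ptr<T>(xs);
  SEXP ys = PROTECT(alloc_tensor_raw<T>(H, W, cout, N));
  T *y = data_ptr<T>(ys);
  std::vector<T> wt = cast_par<T>(w);
  std::vector<T> bt = cast_par<T>(bias);
  const bool has_bias = static_cast<int>(bt.size()) == cout;
  const bool direct3 = (kh == 3 && kw == 3);
  arma::Mat<T> Wf(wt.data(), R, cout, false, true);
  arma::Mat<T> col;
  if (!(kh == 1 && kw == 1) && !direct3) col.set_size(HW, R);
  std::vector<T> acc;
  for (int n = 0; n < N; ++n) {
    const T *xn = x + static_cast<size_t>(n) * HW * C;
    T *yn = y + static_cast<size_t>(n) * HW * cout;
    if (direct3) {
      conv3x3_fwd_sample<T>(xn, H, W, cin, cout, dil, wt.data(),
                            has_bias ? bt.data() : nullptr, yn, acc);
      continue;
    }
    arma::Mat<T> Y(yn, HW, cout, false, true);
    if (kh == 1 && kw == 1) {
      const arma::Mat<T> X(const_cast<T *>(xn), HW, cin, false, true);
      Y = X * Wf;
    } else {
      im2col<T>(xn, H, W, cin, kh, kw, dil, col);
      Y = col * Wf;
    }
    if (has_bias)
      for (int co = 0; co < cout; ++co) Y.col(co) += bt[co];
  }
  UNPROTECT(1);
  return ys;
}

// [[Rcpp::export]]
SEXP cpp_conv_fwd(SEXP x, NumericVector w, NumericVector bias, int dil) {
  return is_f32(x) ? conv_fwd_t<float>(x, w, bias, dil)
                   : conv_fwd_t<double>(x, w, bias, dil);
}

template <typename T>
static List conv_bwd_t(SEXP xs, const NumericVector &w, SEXP dys, int dil,
                       bool want_dx, SEXP daccum, bool want_dw) {
  IntegerVector xd = dims4(xs);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int HW = H * W, R = kh * kw * cin;
  const T *x = data_ptr<T>(xs);
  const T *dy = data_ptr<T>(dys);
  std::vector<T> wt = cast_par<T>(w);
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  NumericVector dbv(cout);
  SEXP dxs = R_NilValue;
  T *dxp = nullptr;
  int dstride = cin;
  if (want_dx) {
    if (!Rf_isNull(daccum)) {
      IntegerVector dd = dims4(daccum);
      if (dd[0] != H || dd[1] != W || dd[3] != N || dd[2] < cin)
        stop("conv bwd: accumulation buffer has wrong shape");
      if (is_f32(daccum) != is_f32(xs)) stop("conv bwd: precision mismatch");
      dxp = data_ptr<T>(daccum);
      dstride = dd[2];
    } else {
      dxs = PROTECT(alloc_tensor<T>(H, W, cin, N));
      dxp = data_ptr<T>(dxs);
    }
  }
  const bool direct3 = (kh == 3 && kw == 3);
  arma::Mat<T> Wf(wt.data(), R, cout, false, true);
  arma::Mat<T> col, dcol;
  if (!(kh == 1 && kw == 1) && !direct3) {
    col.set_size(HW, R);
    dcol.set_size(HW, R);
  }
  // double accumulators for the parameter gradients
  arma::mat dW(dwv.begin(), R, cout, false, true);
  arma::Mat<T> dWt(R, cout, arma::fill::zeros);
  arma::Row<T> dbt(cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const T *xn = x + static_cast<size_t>(n) * HW * C;
    const T *dyn = dy + static_cast<size_t>(n) * HW * cout;
    if (direct3) {
      conv3x3_bwd_sample<T>(xn, dyn, H, W, cin, cout, dil, wt.data(),
                            dxp ? dxp + static_cast<size_t>(n) * HW * dstride
                                : nullptr,
                            dwv.begin(), dbv.begin());
      continue;
    }
    const arma::Mat<T> dY(const_cast<T *>(dyn), HW, cout, false, true);
    dbt += arma::sum(dY, 0);
    if (kh == 1 && kw == 1) {
      const arma::Mat<T> X(const_cast<T *>(xn), HW, cin, false, true);
      if (want_dw) dWt += X.t() * dY;
      if (dxp) {
        arma::Mat<T> dX(dxp + static_cast<size_t>(n) * HW * dstride,
                        HW, cin, false, true);
        dX += dY * Wf.t();
      }
    } else {
      im2col<T>(xn, H, W, cin, kh, kw, dil, col);
      if (want_dw) dWt += col.t() * dY;
      if (dxp) {
        dcol = dY * Wf.t();
        col2im_acc<T>(dcol, H, W, cin, kh, kw, dil,
                      dxp + static_cast<size_t>(n) * HW * dstride);
      }
    }
  }
  if (!direct3) {
    for (int i = 0; i < R * cout; ++i) dW[i] += dWt[i];
    for (int co = 0; co < cout; ++co) dbv[co] += dbt[co];
  }
  List out = List::create(_["dw"] = dwv, _["db"] = dbv,
                          _["dx"] = dxs);
  if (want_dx && Rf_isNull(daccum)) UNPROTECT(1);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(SEXP x, NumericVector w, SEXP dy, int dil, bool want_dx,
                  SEXP daccum, bool want_dw = true) {
  return is_f32(x) ? conv_bwd_t<float>(x, w, dy, dil, want_dx, daccum, want_dw)
                   : conv_bwd_t<double>(x, w, dy, dil, want_dx, daccum,
                                        want_dw);
}

// ---- fused BatchNorm + ReLU -----------------------------------------------

template <typename T>
static List bn_relu_fwd_t(SEXP xs, int cin, const NumericVector &gamma,
                          const NumericVector &beta,
                          const NumericVector &rmean,
                          const NumericVector &rvar, bool training,
                          double momentum, double eps, SEXP stats) {
  NumericVector pre_mean, pre_var;
  bool have_stats = false;
  if (!Rf_isNull(stats)) {
    List st(stats);
    pre_mean = st["mean"];
    pre_var = st["var"];
    if (pre_mean.size() < cin) stop("bn: precomputed stats too short");
    have_stats = true;
  }
  IntegerVector xd = dims4(xs);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (cin > C) stop("bn: cin exceeds available channels");
  const int HW = H * W;
  const double cnt = static_cast<double>(HW) * N;
  const T *x = data_ptr<T>(xs);
  SEXP ys = PROTECT(alloc_tensor_raw<T>(H, W, cin, N));
  T *y = data_ptr<T>(ys);
  NumericVector mean(cin), invstd(cin);
  NumericVector rm = clone(rmean), rv = clone(rvar);
  for (int c = 0; c < cin; ++c) {
    double m, v;
    if (training && have_stats) {
      m = pre_mean[c];
      v = pre_var[c];
      rm[c] = (1 - momentum) * rm[c] + momentum * m;
      rv[c] = (1 - momentum) * rv[c] + momentum * v;
    } else if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const T *__restrict p = x + HW * (static_cast<size_t>(C) * n + c);
        T ps = T(0), ps2 = T(0);
        for (int i = 0; i < HW; ++i) {
          const T t = p[i];
          ps += t;
          ps2 += t * t;
        }
        s += static_cast<double>(ps);
        s2 += static_cast<double>(ps2);
      }
      m = s / cnt;
      v = s2 / cnt - m * m;
      if (v < 0) v = 0;
      rm[c] = (1 - momentum) * rm[c] + momentum * m;
      rv[c] = (1 - momentum) * rv[c] + momentum * v;
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mean[c] = m;
    invstd[c] = is;
    const T a = static_cast<T>(gamma[c] * is);
    const T b = static_cast<T>(beta[c] - gamma[c] * is * m);
    for (int n = 0; n < N; ++n) {
      const T *__restrict p = x + HW * (static_cast<size_t>(C) * n + c);
      T *__restrict q = y + HW * (static_cast<size_t>(cin) * n + c);
      for (int i = 0; i < HW; ++i) {
        const T t = a * p[i] + b;
        q[i] = t > T(0) ? t : T(0);
      }
    }
  }
  List out = List::create(_["y"] = ys, _["mean"] = mean,
                          _["invstd"] = invstd, _["rmean"] = rm,
                          _["rvar"] = rv);
  UNPROTECT(1);
  return out;
}

// [[Rcpp::export]]
List cpp_bn_relu_fwd(SEXP x, int cin, NumericVector gamma, NumericVector beta,
                     NumericVector rmean, NumericVector rvar, bool training,
                     double momentum, double eps,
                     SEXP stats = R_NilValue) {
  return is_f32(x)
    ? bn_relu_fwd_t<float>(x, cin, gamma, beta, rmean, rvar, training,
                           momentum, eps, stats)
    : bn_relu_fwd_t<double>(x, cin, gamma, beta, rmean, rvar, training,
                            momentum, eps, stats);
}

// Batch mean and (biased) variance of channels [c_off, c_off+cs) of a
// tensor, over (H, W, N) -- used to share statistics across the batch-norm
// layers of a dense block, whose inputs alias the same buffer.
template <typename T>
static List channel_stats_t(SEXP xs, int c_off, int cs) {
  IntegerVector xd = dims4(xs);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HW = H * W;
  const double cnt = static_cast<double>(HW) * N;
  const T *x = data_ptr<T>(xs);
  NumericVector mean(cs), var(cs);
  for (int c = 0; c < cs; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const T *__restrict p =
        x + HW * (static_cast<size_t>(C) * n + c_off + c);
      T ps = T(0), ps2 = T(0);
      for (int i = 0; i < HW; ++i) {
        const T t = p[i];
        ps += t;
        ps2 += t * t;
      }
      s += static_cast<double>(ps);
      s2 += static_cast<double>(ps2);
    }
    const double m = s / cnt;
    double v = s2 / cnt - m * m;
    if (v < 0) v = 0;
    mean[c] = m;
    var[c] = v;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_channel_stats(SEXP x, int c_off, int cs) {
  return is_f32(x) ? channel_stats_t<float>(x, c_off, cs)
                   : channel_stats_t<double>(x, c_off, cs);
}

template <typename T>
static List bn_relu_bwd_t(SEXP xs, int cin, const NumericVector &gamma,
                          SEXP dys, SEXP ys, const NumericVector &mean,
                          const NumericVector &invstd, SEXP daccum,
                          bool training) {
  IntegerVector xd = dims4(xs);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector dd = dims4(daccum);
  if (dd[0] != H || dd[1] != W || dd[3] != N || dd[2] < cin)
    stop("bn bwd: accumulation buffer has wrong shape");
  const int Cd = dd[2];
  const int HW = H * W;
  const double cnt = static_cast<double>(HW) * N;
  const T *x = data_ptr<T>(xs);
  const T *y = data_ptr<T>(ys);
  const T *dy = data_ptr<T>(dys);
  T *da = data_ptr<T>(daccum);
  NumericVector dgamma(cin), dbeta(cin);
  for (int c = 0; c < cin; ++c) {
    const double m = mean[c], is = invstd[c];
    double s1 = 0.0, s2 = 0.0;
    const T mT0 = static_cast<T>(m), isT0 = static_cast<T>(is);
    for (int n = 0; n < N; ++n) {
      const T *__restrict xp = x + HW * (static_cast<size_t>(C) * n + c);
      const T *__restrict yp = y + HW * (static_cast<size_t>(cin) * n + c);
      const T *__restrict dp = dy + HW * (static_cast<size_t>(cin) * n + c);
      T p1 = T(0), p2 = T(0);
      for (int i = 0; i < HW; ++i) {
        const T g = yp[i] > T(0) ? dp[i] : T(0);
        p1 += g;
        p2 += g * (xp[i] - mT0) * isT0;
      }
      s1 += static_cast<double>(p1);
      s2 += static_cast<double>(p2);
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const T k1 = static_cast<T>(s1 / cnt), k2 = static_cast<T>(s2 / cnt);
    const T gis = static_cast<T>(gamma[c] * is);
    const T mT = static_cast<T>(m), isT = static_cast<T>(is);
    for (int n = 0; n < N; ++n) {
      const T *__restrict xp = x + HW * (static_cast<size_t>(C) * n + c);
      const T *__restrict yp = y + HW * (static_cast<size_t>(cin) * n + c);
      const T *__restrict dp = dy + HW * (static_cast<size_t>(cin) * n + c);
      T *__restrict ap = da + HW * (static_cast<size_t>(Cd) * n + c);
      if (training) {
        for (int i = 0; i < HW; ++i) {
          const T g = yp[i] > T(0) ? dp[i] : T(0);
          const T xh = (xp[i] - mT) * isT;
          ap[i] += gis * (g - k1 - xh * k2);
        }
      } else {
        for (int i = 0; i < HW; ++i)
          ap[i] += gis * (yp[i] > T(0) ? dp[i] : T(0));
      }
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List cpp_bn_relu_bwd(SEXP x, int cin, NumericVector gamma, SEXP dy, SEXP y,
                     NumericVector mean, NumericVector invstd, SEXP daccum,
                     bool training) {
  return is_f32(x)
    ? bn_relu_bwd_t<float>(x, cin, gamma, dy, y, mean, invstd, daccum,
                           training)
    : bn_relu_bwd_t<double>(x, cin, gamma, dy, y, mean, invstd, daccum,
                            training);
}

// ---- dropout --------------------------------------------------------------

// Inverted dropout driven by the R RNG (so set.seed() reproduces runs).
// Mutates the activations in place (they are private intermediates) and
// returns the mask as a raw vector.
template <typename T>
static RawVector dropout_fwd_t(SEXP xs, double rate) {
  T *x = data_ptr<T>(xs);
  const R_xlen_t n = Rf_xlength(xs);
  RawVector mask(n);
  const double keep = 1.0 - rate;
  const T scale = static_cast<T>(1.0 / keep);
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool k = unif_rand() < keep;
    mask[i] = k;
    x[i] = k ? x[i] * scale : T(0);
  }
  PutRNGstate();
  return mask;
}

// [[Rcpp::export]]
RawVector cpp_dropout_fwd(SEXP x, double rate) {
  return is_f32(x) ? dropout_fwd_t<float>(x, rate)
                   : dropout_fwd_t<double>(x, rate);
}

// In-place backward: dy is always a private buffer in this package.
template <typename T>
static void dropout_bwd_t(SEXP dys, const RawVector &mask, double rate) {
  T *dy = data_ptr<T>(dys);
  const T scale = static_cast<T>(1.0 / (1.0 - rate));
  const R_xlen_t n = Rf_xlength(dys);
  for (R_xlen_t i = 0; i < n; ++i) dy[i] = mask[i] ? dy[i] * scale : T(0);
}

// [[Rcpp::export]]
void cpp_dropout_bwd(SEXP dy, RawVector mask, double rate) {
  if (is_f32(dy)) dropout_bwd_t<float>(dy, mask, rate);
  else dropout_bwd_t<double>(dy, mask, rate);
}

// ---- pooling ---------------------------------------------------------------

template <typename T>
static SEXP avgpool2_fwd_t(SEXP xs) {
  IntegerVector xd = dims4(xs);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2, HW = H * W;
  const T *x = data_ptr<T>(xs);
  SEXP ys = PROTECT(alloc_tensor_raw<T>(Ho, Wo, C, N));
  T *y = data_ptr<T>(ys);
  for (int cn = 0; cn < C * N; ++cn) {
    const T *p = x + static_cast<size_t>(cn) * HW;
    T *q = y + static_cast<size_t>(cn) * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        q[h + static_cast<size_t>(w) * Ho] = static_cast<T>(0.25) *
          (p[2 * h + static_cast<size_t>(2 * w) * H] +
           p[2 * h + 1 + static_cast<size_t>(2 * w) * H] +
           p[2 * h + static_cast<size_t>(2 * w + 1) * H] +
           p[2 * h + 1 + static_cast<size_t>(2 * w + 1) * H]);
  }
  UNPROTECT(1);
  return ys;
}

// [[Rcpp::export]]
SEXP cpp_avgpool2_fwd(SEXP x) {
  return is_f32(x) ? avgpool2_fwd_t<float>(x) : avgpool2_fwd_t<double>(x);
}

template <typename T>
static SEXP avgpool2_bwd_t(SEXP dys, int H, int W) {
  IntegerVector yd = dims4(dys);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const T *dy = data_ptr<T>(dys);
  SEXP dxs = PROTECT(alloc_tensor<T>(H, W, C, N));
  T *dx = data_ptr<T>(dxs);
  for (int cn = 0; cn < C * N; ++cn) {
    const T *q = dy + static_cast<size_t>(cn) * Ho * Wo;
    T *p = dx + static_cast<size_t>(cn) * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const T g = static_cast<T>(0.25) * q[h + static_cast<size_t>(w) * Ho];
        p[2 * h + static_cast<size_t>(2 * w) * H] += g;
        p[2 * h + 1 + static_cast<size_t>(2 * w) * H] += g;
        p[2 * h + static_cast<size_t>(2 * w + 1) * H] += g;
        p[2 * h + 1 + static_cast<size_t>(2 * w + 1) * H] += g;
      }
  }
  UNPROTECT(1);
  return dxs;
}

// [[Rcpp::export]]
SEXP cpp_avgpool2_bwd(SEXP dy, int H, int W) {
  return is_f32(dy) ? avgpool2_bwd_t<float>(dy, H, W)
                    : avgpool2_bwd_t<double>(dy, H, W);
}

// Adaptive average pooling to bins x bins (pyramid levels): bin i covers
// input rows [floor(i*H/bins), ceil((i+1)*H/bins)).
template <typename T>
static SEXP adaptive_fwd_t(SEXP xs, int bins) {
  IntegerVector xd = dims4(xs);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (bins > H || bins > W) stop("pooling bins exceed input size");
  const T *x = data_ptr<T>(xs);
  SEXP ys = PROTECT(alloc_tensor_raw<T>(bins, bins, C, N));
  T *y = data_ptr<T>(ys);
  for (int cn = 0; cn < C * N; ++cn) {
    const T *p = x + static_cast<size_t>(cn) * H * W;
    T *q = y + static_cast<size_t>(cn) * bins * bins;
    for (int bw = 0; bw < bins; ++bw) {
      const int w0 = (bw * W) / bins, w1 = ((bw + 1) * W + bins - 1) / bins;
      for (int bh = 0; bh < bins; ++bh) {
        const int h0 = (bh * H) / bins, h1 = ((bh + 1) * H + bins - 1) / bins;
        double s = 0.0;
        for (int w = w0; w < w1; ++w)
          for (int h = h0; h < h1; ++h) s += p[h + static_cast<size_t>(w) * H];
        q[bh + static_cast<size_t>(bw) * bins] =
          static_cast<T>(s / ((w1 - w0) * (h1 - h0)));
      }
    }
  }
  UNPROTECT(1);
  return ys;
}

// [[Rcpp::export]]
SEXP cpp_adaptive_avgpool_fwd(SEXP x, int bins) {
  return is_f32(x) ? adaptive_fwd_t<float>(x, bins)
                   : adaptive_fwd_t<double>(x, bins);
}

template <typename T>
static SEXP adaptive_bwd_t(SEXP dys, int H, int W) {
  IntegerVector yd = dims4(dys);
  const int bins = yd[0], C = yd[2], N = yd[3];
  const T *dy = data_ptr<T>(dys);
  SEXP dxs = PROTECT(alloc_tensor<T>(H, W, C, N));
  T *dx = data_ptr<T>(dxs);
  for (int cn = 0; cn < C * N; ++cn) {
    const T *q = dy + static_cast<size_t>(cn) * bins * bins;
    T *p = dx + static_cast<size_t>(cn) * H * W;
    for (int bw = 0; bw < bins; ++bw) {
      const int w0 = (bw * W) / bins, w1 = ((bw + 1) * W + bins - 1) / bins;
      for (int bh = 0; bh < bins; ++bh) {
        const int h0 = (bh * H) / bins, h1 = ((bh + 1) * H + bins - 1) / bins;
        const T g = q[bh + static_cast<size_t>(bw) * bins] /
          static_cast<T>((w1 - w0) * (h1 - h0));
        for (int w = w0; w < w1; ++w)
          for (int h = h0; h < h1; ++h) p[h + static_cast<size_t>(w) * H] += g;
      }
    }
  }
  UNPROTECT(1);
  return dxs;
}

// [[Rcpp::export]]
SEXP cpp_adaptive_avgpool_bwd(SEXP dy, int H, int W) {
  return is_f32(dy) ? adaptive_bwd_t<float>(dy, H, W)
                    : adaptive_bwd_t<double>(dy, H, W);
}

// ---- bilinear resampling ---------------------------------------------------

struct LinCoef { int i0, i1; double f; };

static std::vector<LinCoef> bilinear_coef(int in, int out) {
  std::vector<LinCoef> cf(out);
  const double scale = static_cast<double>(in) / out;
  for (int j = 0; j < out; ++j) {
    double src = (j + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int i0 = static_cast<int>(std::floor(src));
    if (i0 > in - 1) i0 = in - 1;
    int i1 = std::min(i0 + 1, in - 1);
    cf[j] = {i0, i1, src - i0};
  }
  return cf;
}

template <typename T>
static SEXP bilinear_fwd_t(SEXP xs, int oh, int ow) {
  IntegerVector xd = dims4(xs);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const T *x = data_ptr<T>(xs);
  SEXP ys = PROTECT(alloc_tensor_raw<T>(oh, ow, C, N));
  T *y = data_ptr<T>(ys);
  std::vector<LinCoef> ch = bilinear_coef(H, oh), cw = bilinear_coef(W, ow);
  for (int cn = 0; cn < C * N; ++cn) {
    const T *p = x + static_cast<size_t>(cn) * H * W;
    T *q = y + static_cast<size_t>(cn) * oh * ow;
    for (int w = 0; w < ow; ++w) {
      const LinCoef &cww = cw[w];
      const T *c0 = p + static_cast<size_t>(cww.i0) * H;
      const T *c1 = p + static_cast<size_t>(cww.i1) * H;
      for (int h = 0; h < oh; ++h) {
        const LinCoef &chh = ch[h];
        const double v0 = c0[chh.i0] * (1 - chh.f) + c0[chh.i1] * chh.f;
        const double v1 = c1[chh.i0] * (1 - chh.f) + c1[chh.i1] * chh.f;
        q[h + static_cast<size_t>(w) * oh] =
          static_cast<T>(v0 * (1 - cww.f) + v1 * cww.f);
      }
    }
  }
  UNPROTECT(1);
  return ys;
}

// [[Rcpp::export]]
SEXP cpp_bilinear_fwd(SEXP x, int oh, int ow) {
  return is_f32(x) ? bilinear_fwd_t<float>(x, oh, ow)
                   : bilinear_fwd_t<double>(x, oh, ow);
}

template <typename T>
static SEXP bilinear_bwd_t(SEXP dys, int H, int W) {
  IntegerVector yd = dims4(dys);
  const int oh = yd[0], ow = yd[1], C = yd[2], N = yd[3];
  const T *dy = data_ptr<T>(dys);
  SEXP dxs = PROTECT(alloc_tensor<T>(H, W, C, N));
  T *dx = data_ptr<T>(dxs);
  std::vector<LinCoef> ch = bilinear_coef(H, oh), cw = bilinear_coef(W, ow);
  for (int cn = 0; cn < C * N; ++cn) {
    const T *q = dy + static_cast<size_t>(cn) * oh * ow;
    T *p = dx + static_cast<size_t>(cn) * H * W;
    for (int w = 0; w < ow; ++w) {
      const LinCoef &cww = cw[w];
      T *c0 = p + static_cast<size_t>(cww.i0) * H;
      T *c1 = p + static_cast<size_t>(cww.i1) * H;
      for (int h = 0; h < oh; ++h) {
        const LinCoef &chh = ch[h];
        const double g = q[h + static_cast<size_t>(w) * oh];
        c0[chh.i0] += static_cast<T>(g * (1 - chh.f) * (1 - cww.f));
        c0[chh.i1] += static_cast<T>(g * chh.f * (1 - cww.f));
        c1[chh.i0] += static_cast<T>(g * (1 - chh.f) * cww.f);
        c1[chh.i1] += static_cast<T>(g * chh.f * cww.f);
      }
    }
  }
  UNPROTECT(1);
  return dxs;
}

// [[Rcpp::export]]
SEXP cpp_bilinear_bwd(SEXP dy, int H, int W) {
  return is_f32(dy) ? bilinear_bwd_t<float>(dy, H, W)
                    : bilinear_bwd_t<double>(dy, H, W);
}

// ---- structural helpers ----------------------------------------------------

// Copy `src` (H, W, cs, N) into channels [c_off, c_off+cs) of `buf`,
// mutating `buf` in place (buf is a private working buffer).
// [[Rcpp::export]]
void cpp_write_channels(SEXP buf, SEXP src, int c_off) {
  IntegerVector bd = dims4(buf), sd = dims4(src);
  const int H = bd[0], W = bd[1], C = bd[2], N = bd[3], cs = sd[2];
  if (sd[0] != H || sd[1] != W || sd[3] != N || c_off + cs > C)
    stop("write_channels: shape mismatch");
  if (is_f32(buf) != is_f32(src)) stop("write_channels: precision mismatch");
  const size_t HW = static_cast<size_t>(H) * W;
  const size_t esz = is_f32(buf) ? 4 : 8;
  char *b = reinterpret_cast<char *>(DATAPTR(buf));
  const char *s = reinterpret_cast<const char *>(DATAPTR(src));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cs; ++c)
      memcpy(b + esz * HW * (static_cast<size_t>(C) * n + c_off + c),
             s + esz * HW * (static_cast<size_t>(cs) * n + c), esz * HW);
}

// Extract channels [c_off, c_off+cs) of `buf` as a new tensor.
// [[Rcpp::export]]
SEXP cpp_slice_channels(SEXP buf, int c_off, int cs) {
  IntegerVector bd = dims4(buf);
  const int H = bd[0], W = bd[1], C = bd[2], N = bd[3];
  if (c_off + cs > C) stop("slice_channels: out of range");
  const size_t HW = static_cast<size_t>(H) * W;
  SEXP out = PROTECT(is_f32(buf) ? alloc_tensor_raw<float>(H, W, cs, N)
                                 : alloc_tensor_raw<double>(H, W, cs, N));
  const size_t esz = is_f32(buf) ? 4 : 8;
  const char *b = reinterpret_cast<const char *>(DATAPTR(buf));
  char *o = reinterpret_cast<char *>(DATAPTR(out));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cs; ++c)
      memcpy(o + esz * HW * (static_cast<size_t>(cs) * n + c),
             b + esz * HW * (static_cast<size_t>(C) * n + c_off + c), esz * HW);
  UNPROTECT(1);
  return out;
}

// In-place dst += src for equal-shape tensors.
// [[Rcpp::export]]
void cpp_add_inplace(SEXP dst, SEXP src) {
  if (Rf_xlength(dst) != Rf_xlength(src)) stop("add_inplace: length mismatch");
  if (is_f32(dst) != is_f32(src)) stop("add_inplace: precision mismatch");
  const R_xlen_t n = Rf_xlength(dst);
  if (is_f32(dst)) {
    float *__restrict d = data_ptr<float>(dst);
    const float *__restrict s = data_ptr<float>(src);
    for (R_xlen_t i = 0; i < n; ++i) d[i] += s[i];
  } else {
    double *__restrict d = REAL(dst);
    const double *__restrict s = REAL(src);
    for (R_xlen_t i = 0; i < n; ++i) d[i] += s[i];
  }
}
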