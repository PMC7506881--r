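#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Persistent scratch for im2col column matrices: they are an order of
// magnitude larger than the activations, and reallocating them through
// the R heap on every minibatch costs more (page faults) than the GEMMs
// they feed.  R is single-threaded, so plain statics are safe.
static std::vector<double> g_cols, g_dcols;

static void im2col_buf(const double* xp, double* op, int h, int w, int n,
                       int c, int k, int pad) {
  size_t N = (size_t)h * w * n;
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        size_t col = (size_t)ki + k * ((size_t)kj + k * ch);
        double* ocol = op + N * col;
        const double* xcol = xp + N * ch;
        for (int ni = 0; ni < n; ++ni)
          for (int j = 0; j < w; ++j) {
            int xj = j + kj - pad;
            double* dst = ocol + (size_t)h * (j + (size_t)w * ni);
            if (xj < 0 || xj >= w) {
              std::fill(dst, dst + h, 0.0);
              continue;
            }
            const double* src = xcol + (size_t)h * (xj + (size_t)w * ni);
            int di = ki - pad;
            int i0 = std::max(0, -di), i1 = std::min(h, h - di);
            if (i0 > 0) std::fill(dst, dst + i0, 0.0);
            if (i1 > i0) std::copy(src + i0 + di, src + i1 + di, dst + i0);
            if (i1 < h) std::fill(dst + i1, dst + h, 0.0);
          }
      }
}

static void col2im_buf(const double* op, double* xp, int h, int w, int n,
                       int c, int k, int pad) {
  size_t N = (size_t)h * w * n;
  std::fill(xp, xp + N * c, 0.0);
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        size_t col = (size_t)ki + k * ((size_t)kj + k * ch);
        const double* ocol = op + N * col;
        double* xcol = xp + N * ch;
        for (int ni = 0; ni < n; ++ni)
          for (int j = 0; j < w; ++j) {
            int xj = j + kj - pad;
            if (xj < 0 || xj >= w) continue;
            const double* src = ocol + (size_t)h * (j + (size_t)w * ni);
            double* dst = xcol + (size_t)h * (xj + (size_t)w * ni);
            int di = ki - pad;
            int i0 = std::max(0, -di), i1 = std::min(h, h - di);
            for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
          }
      }
}

// y = im2col(x) %*% W + b, all in one call.
// [[Rcpp::export]]
NumericMatrix cpp_conv_fw(NumericMatrix x, int h, int w, int n,
                          NumericMatrix W, NumericVector b, int k, int pad) {
  int c = x.ncol(), oc = W.ncol(), kkc = W.nrow();
  size_t N = (size_t)h * w * n;
  g_cols.resize(N * kkc);
  im2col_buf(x.begin(), g_cols.data(), h, w, n, c, k, pad);
  NumericMatrix y((int)N, oc);
  int m_ = (int)N;
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m_, &oc, &kkc, &one, g_cols.data(), &m_,
                  W.begin(), &kkc, &zero, y.begin(), &m_ FCONE FCONE);
  for (int ch = 0; ch < oc; ++ch) {
    double* yc = y.begin() + N * ch;
    double bv = b[ch];
    for (size_t i = 0; i < N; ++i) yc[i] += bv;
  }
  return y;
}

// Gradients of the convolution: dW = im2col(a)^T dy, db = colSums(dy),
// and (optionally) da = col2im(dy W^T).
// [[Rcpp::export]]
List cpp_conv_bw(NumericMatrix dy, NumericMatrix a, int h, int w, int n,
                 NumericMatrix W, int k, int pad, bool need_dx) {
  int c = a.ncol(), oc = W.ncol(), kkc = W.nrow();
  size_t N = (size_t)h * w * n;
  g_cols.resize(N * kkc);
  im2col_buf(a.begin(), g_cols.data(), h, w, n, c, k, pad);
  NumericMatrix dW(kkc, oc);
  NumericVector db(oc);
  int m_ = (int)N;
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &kkc, &oc, &m_, &one, g_cols.data(), &m_,
                  dy.begin(), &m_, &zero, dW.begin(), &kkc FCONE FCONE);
  for (int ch = 0; ch < oc; ++ch) {
    const double* dyc = dy.begin() + N * ch;
    double s = 0;
    for (size_t i = 0; i < N; ++i) s += dyc[i];
    db[ch] = s;
  }
  if (!need_dx)
    return List::create(_["dW"] = dW, _["db"] = db);
  g_dcols.resize(N * kkc);
  F77_CALL(dgemm)("N", "T", &m_, &kkc, &oc, &one, dy.begin(), &m_,
                  W.begin(), &kkc, &zero, g_dcols.data(), &m_ FCONE FCONE);
  NumericMatrix dx((int)N, c);
  col2im_buf(g_dcols.data(), dx.begin(), h, w, n, c, k, pad);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Activations are "channel matrices": N x c with N = h*w*n, rows indexed
// i + h*(j + w*sample) (column-major spatial blocks per sample), one
// column per channel.  This layout makes convolution an im2col + GEMM
// with no transposes, channel concatenation a cbind, and batch-norm a
// column operation.

// im2col for same-padded stride-1 convolution.  Output: N x (k*k*c),
// column index ki + k*(kj + k*ch); writes are fully sequential.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix x, int h, int w, int n, int k, int pad) {
  int c = x.ncol();
  size_t N = (size_t)h * w * n;
  NumericMatrix out((int)N, k * k * c);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        size_t col = (size_t)ki + k * ((size_t)kj + k * ch);
        double* ocol = op + N * col;
        const double* xcol = xp + N * ch;
        for (int ni = 0; ni < n; ++ni)
          for (int j = 0; j < w; ++j) {
            int xj = j + kj - pad;
            double* dst = ocol + (size_t)h * (j + (size_t)w * ni);
            if (xj < 0 || xj >= w) {
              std::fill(dst, dst + h, 0.0);
              continue;
            }
            const double* src = xcol + (size_t)h * (xj + (size_t)w * ni);
            int di = ki - pad;
            int i0 = std::max(0, -di), i1 = std::min(h, h - di);
            if (i0 > 0) std::fill(dst, dst + i0, 0.0);
            if (i1 > i0) std::copy(src + i0 + di, src + i1 + di, dst + i0);
            if (i1 < h) std::fill(dst + i1, dst + h, 0.0);
          }
      }
  return out;
}

// Scatter-add adjoint of cpp_im2col.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(NumericMatrix cols, int h, int w, int n, int c,
                         int k, int pad) {
  size_t N = (size_t)h * w * n;
  NumericMatrix x((int)N, c);
  double* xp = x.begin();
  const double* op = cols.begin();
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        size_t col = (size_t)ki + k * ((size_t)kj + k * ch);
        const double* ocol = op + N * col;
        double* xcol = xp + N * ch;
        for (int ni = 0; ni < n; ++ni)
          for (int j = 0; j < w; ++j) {
            int xj = j + kj - pad;
            if (xj < 0 || xj >= w) continue;
            const double* src = ocol + (size_t)h * (j + (size_t)w * ni);
            double* dst = xcol + (size_t)h * (xj + (size_t)w * ni);
            int di = ki - pad;
            int i0 = std::max(0, -di), i1 = std::min(h, h - di);
            for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
          }
      }
  return x;
}

// Fused batch-norm + ReLU forward.  training: batch statistics are
// computed; otherwise the supplied running statistics are used.
// [[Rcpp::export]]
List cpp_bn_relu_fw(NumericMatrix x, NumericVector gamma, NumericVector beta,
                    NumericVector run_mean, NumericVector run_var,
                    bool training, double eps) {
  int c = x.ncol();
  size_t N = x.nrow();
  NumericMatrix a((int)N, c);
  NumericVector mu(c), istd(c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = x.begin() + N * ch;
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (size_t i = 0; i < N; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      m = s / N;
      v = s2 / N - m * m;
      if (v < 0) v = 0;
    } else {
      m = run_mean[ch];
      v = run_var[ch];
    }
    mu[ch] = m;
    double is = 1.0 / std::sqrt(v + eps);
    istd[ch] = is;
    double sc = gamma[ch] * is, sh = beta[ch] - sc * m;
    double* ac = a.begin() + N * ch;
    for (size_t i = 0; i < N; ++i) {
      double z = xc[i] * sc + sh;
      ac[i] = z > 0 ? z : 0;
    }
  }
  return List::create(_["a"] = a, _["mu"] = mu, _["istd"] = istd);
}

// Fused ReLU + batch-norm backward.  `a` is the cached forward output
// (its positivity is the ReLU mask).  Returns dx, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_relu_bw(NumericMatrix da, NumericMatrix x, NumericMatrix a,
                    NumericVector gamma, NumericVector mu, NumericVector istd,
                    bool need_dx) {
  int c = x.ncol();
  size_t N = x.nrow();
  NumericVector dgamma(c), dbeta(c);
  NumericMatrix dx = need_dx ? NumericMatrix((int)N, c) : NumericMatrix(0, 0);
  for (int ch = 0; ch < c; ++ch) {
    const double* dac = da.begin() + N * ch;
    const double* xc = x.begin() + N * ch;
    const double* ac = a.begin() + N * ch;
    double m = mu[ch], is = istd[ch];
    double s1 = 0, s2 = 0;
    for (size_t i = 0; i < N; ++i) {
      if (ac[i] <= 0) continue;
      double xh = (xc[i] - m) * is;
      s1 += dac[i];
      s2 += dac[i] * xh;
    }
    dbeta[ch] = s1;
    dgamma[ch] = s2;
    if (need_dx) {
      double* dxc = dx.begin() + N * ch;
      double g = gamma[ch] * is, m1 = s1 / N, m2 = s2 / N;
      for (size_t i = 0; i < N; ++i) {
        double dz = ac[i] > 0 ? dac[i] : 0;
        double xh = (xc[i] - m) * is;
        dxc[i] = g * (dz - m1 - xh * m2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Pooling with ceiling output size; windows clipped to the input.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericMatrix x, int h, int w, int n, int k, int stride) {
  int c = x.ncol();
  int oh = (h + stride - 1) / stride, ow = (w + stride - 1) / stride;
  size_t M = (size_t)oh * ow * n;
  NumericMatrix out((int)M, c);
  IntegerMatrix arg((int)M, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = x.begin() + (size_t)h * w * n * ch;
    double* oc = out.begin() + M * ch;
    int* gc = arg.begin() + M * ch;
    for (int ni = 0; ni < n; ++ni) {
      const double* xs = xc + (size_t)h * w * ni;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          int i0 = i * stride, j0 = j * stride;
          int i1 = std::min(i0 + k, h), j1 = std::min(j0 + k, w);
          double best = R_NegInf;
          int bi = 0;
          for (int jj = j0; jj < j1; ++jj)
            for (int ii = i0; ii < i1; ++ii) {
              double v = xs[ii + (size_t)h * jj];
              if (v > best) { best = v; bi = ii + h * jj; }
            }
          size_t o = (size_t)i + oh * (j + (size_t)ow * ni);
          oc[o] = best;
          gc[o] = bi + h * w * ni;
        }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(NumericMatrix dy, IntegerMatrix argmax, int N) {
  int c = dy.ncol();
  NumericMatrix dx(N, c);
  size_t M = dy.nrow();
  for (int ch = 0; ch < c; ++ch) {
    const double* dyc = dy.begin() + M * ch;
    const int* gc = argmax.begin() + M * ch;
    double* dxc = dx.begin() + (size_t)N * ch;
    for (size_t o = 0; o < M; ++o) dxc[gc[o]] += dyc[o];
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix cpp_avgpool_fw(NumericMatrix x, int h, int w, int n,
                             int k, int stride) {
  int c = x.ncol();
  int oh = (h + stride - 1) / stride, ow = (w + stride - 1) / stride;
  size_t M = (size_t)oh * ow * n;
  NumericMatrix out((int)M, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = x.begin() + (size_t)h * w * n * ch;
    double* oc = out.begin() + M * ch;
    for (int ni = 0; ni < n; ++ni) {
      const double* xs = xc + (size_t)h * w * ni;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          int i0 = i * stride, j0 = j * stride;
          int i1 = std::min(i0 + k, h), j1 = std::min(j0 + k, w);
          double s = 0;
          for (int jj = j0; jj < j1; ++jj)
            for (int ii = i0; ii < i1; ++ii) s += xs[ii + (size_t)h * jj];
          oc[(size_t)i + oh * (j + (size_t)ow * ni)] =
            s / ((i1 - i0) * (j1 - j0));
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_avgpool_bw(NumericMatrix dy, int h, int w, int n,
                             int k, int stride) {
  int c = dy.ncol();
  int oh = (h + stride - 1) / stride, ow = (w + stride - 1) / stride;
  size_t M = (size_t)oh * ow * n;
  NumericMatrix dx(h * w * n, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* dyc = dy.begin() + M * ch;
    double* dxc = dx.begin() + (size_t)h * w * n * ch;
    for (int ni = 0; ni < n; ++ni) {
      double* xs = dxc + (size_t)h * w * ni;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          int i0 = i * stride, j0 = j * stride;
          int i1 = std::min(i0 + k, h), j1 = std::min(j0 + k, w);
          double g = dyc[(size_t)i + oh * (j + (size_t)ow * ni)] /
            ((i1 - i0) * (j1 - j0));
          for (int jj = j0; jj < j1; ++jj)
            for (int ii = i0; ii < i1; ++ii) xs[ii + (size_t)h * jj] += g;
        }
    }
  }
  return dx;
}

// Global max pool over (h, w): returns n x c matrix plus per-entry
// argmax row indices.
// [[Rcpp::export]]
List cpp_gmp_fw(NumericMatrix x, int h, int w, int n) {
  int c = x.ncol();
  NumericMatrix out(n, c);
  IntegerMatrix arg(n, c);
  size_t hw = (size_t)h * w;
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = x.begin() + hw * n * ch;
    for (int ni = 0; ni < n; ++ni) {
      const double* xs = xc + hw * ni;
      double best = R_NegInf;
      int bi = 0;
      for (size_t i = 0; i < hw; ++i)
        if (xs[i] > best) { best = xs[i]; bi = (int)i; }
      out(ni, ch) = best;
      arg(ni, ch) = (int)(bi + hw * ni);
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_gmp_bw(NumericMatrix dy, IntegerMatrix argmax, int N) {
  int c = dy.ncol();
  NumericMatrix dx(N, c);
  for (int ch = 0; ch < c; ++ch) {
    double* dxc = dx.begin() + (size_t)N * ch;
    for (int ni = 0; ni < dy.nrow(); ++ni)
      dxc[argmax(ni, ch)] += dy(ni, ch);
  }
  return dx;
}
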