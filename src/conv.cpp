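// BLAS-backed convolution and batch-normalization kernels.
// Layout: tensors are (h, w, c, n) column-major arrays. For each sample the
// im2col patch matrix is (h*w) x (k*k*cin) so the GEMM result lands directly
// in the output array's per-sample block.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// fill per-sample patch matrix: cols(pix, (ch,kj,ki)) via padded planes
static void fill_cols(const double* xs, int h, int w, int c, int k, int pad,
                      arma::mat& padplane, arma::mat& cols) {
  int hp = h + 2 * pad;
  for (int ch = 0; ch < c; ++ch) {
    padplane.zeros();
    for (int j = 0; j < w; ++j) {
      std::memcpy(padplane.colptr(j + pad) + pad, xs + (size_t)ch * h * w + (size_t)j * h,
                  h * sizeof(double));
    }
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int colidx = ch * k * k + kj * k + ki;
        double* dst = cols.colptr(colidx);
        for (int j = 0; j < w; ++j) {
          std::memcpy(dst + (size_t)j * h, padplane.colptr(j + kj) + ki,
                      h * sizeof(double));
        }
      }
    }
  }
}

// adjoint: scatter patch-gradient matrix back into dx for one sample
static void scatter_cols(const arma::mat& dcols, double* dxs, int h, int w,
                         int c, int k, int pad, arma::mat& padplane) {
  int hp = h + 2 * pad;
  (void)hp;
  for (int ch = 0; ch < c; ++ch) {
    padplane.zeros();
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int colidx = ch * k * k + kj * k + ki;
        const double* src = dcols.colptr(colidx);
        for (int j = 0; j < w; ++j) {
          double* dst = padplane.colptr(j + kj) + ki;
          const double* s = src + (size_t)j * h;
          for (int i = 0; i < h; ++i) dst[i] += s[i];
        }
      }
    }
    for (int j = 0; j < w; ++j) {
      double* dst = dxs + (size_t)ch * h * w + (size_t)j * h;
      const double* s = padplane.colptr(j + pad) + pad;
      for (int i = 0; i < h; ++i) dst[i] += s[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector Wv,
                             NumericVector bv, int pad) {
  IntegerVector xd = x.attr("dim"), wd = Wv.attr("dim");
  int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  int k = wd[0], cout = wd[3];
  int K = k * k * c;
  NumericVector y(static_cast<R_xlen_t>(h) * w * cout * n);
  y.attr("dim") = IntegerVector::create(h, w, cout, n);
  arma::mat Wm(const_cast<double*>(Wv.begin()), K, cout, false, true);
  arma::mat padplane(h + 2 * pad, w + 2 * pad);
  arma::mat cols(h * w, K);
  for (int s = 0; s < n; ++s) {
    fill_cols(x.begin() + (size_t)s * h * w * c, h, w, c, k, pad,
              padplane, cols);
    arma::mat ys(y.begin() + (size_t)s * h * w * cout, h * w, cout,
                 false, true);
    ys = cols * Wm;
    ys.each_row() += arma::rowvec(const_cast<double*>(bv.begin()), cout,
                                  false, true);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector Wv, NumericVector dy,
                    int pad, bool needDx, bool needDw) {
  IntegerVector xd = x.attr("dim"), wd = Wv.attr("dim");
  int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  int k = wd[0], cout = wd[3];
  int K = k * k * c;
  arma::mat Wm(const_cast<double*>(Wv.begin()), K, cout, false, true);
  NumericVector dx, dW;
  arma::mat dWm;
  if (needDw) dWm.zeros(K, cout);
  if (needDx) {
    dx = NumericVector(static_cast<R_xlen_t>(h) * w * c * n);
    dx.attr("dim") = xd;
  }
  NumericVector db(cout);
  arma::mat padplane(h + 2 * pad, w + 2 * pad);
  arma::mat cols(h * w, K);
  arma::mat dcols(h * w, K);
  for (int s = 0; s < n; ++s) {
    arma::mat dys(const_cast<double*>(dy.begin()) + (size_t)s * h * w * cout,
                  h * w, cout, false, true);
    if (needDw) {
      fill_cols(x.begin() + (size_t)s * h * w * c, h, w, c, k, pad,
                padplane, cols);
      dWm += cols.t() * dys;
    }
    if (needDx) {
      dcols = dys * Wm.t();
      scatter_cols(dcols, dx.begin() + (size_t)s * h * w * c, h, w, c, k,
                   pad, padplane);
    }
    arma::rowvec cs = arma::sum(dys, 0);
    for (int co = 0; co < cout; ++co) db[co] += cs[co];
  }
  if (needDw) {
    dW = NumericVector(dWm.begin(), dWm.end());
    dW.attr("dim") = wd;
  }
  return List::create(_["dx"] = needDx ? (SEXP)dx : R_NilValue,
                      _["dW"] = needDw ? (SEXP)dW : R_NilValue,
                      _["db"] = db);
}

// per-channel batch statistics over (h, w, n)
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  size_t hw = (size_t)h * w;
  NumericVector mu(c), va(c);
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double* p = x.begin() + ((size_t)s * c + ch) * hw;
      double acc = 0, acc2 = 0;
      for (size_t i = 0; i < hw; ++i) { acc += p[i]; acc2 += p[i] * p[i]; }
      mu[ch] += acc; va[ch] += acc2;
    }
  double m = (double)hw * n;
  for (int ch = 0; ch < c; ++ch) {
    mu[ch] /= m;
    va[ch] = va[ch] / m - mu[ch] * mu[ch];
    if (va[ch] < 0) va[ch] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = gamma * (x - mu) * invstd + beta
// [[Rcpp::export]]
NumericVector bn_apply_cpp(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector mu,
                           NumericVector invstd) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  size_t hw = (size_t)h * w;
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double* p = x.begin() + ((size_t)s * c + ch) * hw;
      double* q = y.begin() + ((size_t)s * c + ch) * hw;
      double a = gamma[ch] * invstd[ch];
      double b = beta[ch] - a * mu[ch];
      for (size_t i = 0; i < hw; ++i) q[i] = a * p[i] + b;
    }
  return y;
}

// gradients of batch normalization (training mode when train = true)
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector invstd, bool train) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  size_t hw = (size_t)h * w;
  double m = (double)hw * n;
  NumericVector dgamma(c), dbeta(c);
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  // accumulate per-channel sums of dy and dy*xhat
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double* px = x.begin() + ((size_t)s * c + ch) * hw;
      const double* pg = dy.begin() + ((size_t)s * c + ch) * hw;
      double sg = 0, sgx = 0;
      for (size_t i = 0; i < hw; ++i) {
        double xh = (px[i] - mu[ch]) * invstd[ch];
        sg += pg[i];
        sgx += pg[i] * xh;
      }
      dbeta[ch] += sg;
      dgamma[ch] += sgx;
    }
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double* px = x.begin() + ((size_t)s * c + ch) * hw;
      const double* pg = dy.begin() + ((size_t)s * c + ch) * hw;
      double* pd = dx.begin() + ((size_t)s * c + ch) * hw;
      double gi = gamma[ch] * invstd[ch];
      if (train) {
        double mg = dbeta[ch] / m, mgx = dgamma[ch] / m;
        for (size_t i = 0; i < hw; ++i) {
          double xh = (px[i] - mu[ch]) * invstd[ch];
          pd[i] = gi * (pg[i] - mg - xh * mgx);
        }
      } else {
        for (size_t i = 0; i < hw; ++i) pd[i] = gi * pg[i];
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector x, NumericVector g) {
  NumericVector d(x.size());
  d.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  const double* pg = g.begin();
  double* q = d.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? pg[i] : 0;
  return d;
}
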