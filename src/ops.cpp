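// Compiled kernels for the autodiff engine: im2col/col2im convolution
// support, 2x2 max pooling, bilinear resizing (forward + adjoint),
// per-sample dynamic depth-wise convolution, and adaptive max pooling.
// Tensors are R arrays with dim (h, w, c, n), column-major.
#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline int dim_i(const IntegerVector& d, int k) { return d[k]; }

// rows ordered (ki fastest, kj, channel) to match matrix(W, k*k*c, cout)
// for a kernel array of dim (k, k, c, cout); columns ordered (pixel, sample).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int pad) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  int K = k * k * c;
  NumericMatrix out(K, h * w * n);
  const double* px = x.begin();
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        int col = s * h * w + j * h + i;
        double* pout = &out(0, col);
        for (int ch = 0; ch < c; ++ch) {
          const double* base = px + ((size_t)s * c + ch) * h * w;
          for (int kj = 0; kj < k; ++kj) {
            int jj = j + kj - pad;
            for (int ki = 0; ki < k; ++ki) {
              int ii = i + ki - pad;
              double v = 0.0;
              if (ii >= 0 && ii < h && jj >= 0 && jj < w)
                v = base[jj * h + ii];
              pout[ch * k * k + kj * k + ki] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// adjoint of im2col: scatter patch columns back into an (h,w,c,n) array
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int h, int w, int c, int n,
                         int k, int pad) {
  NumericVector out(static_cast<R_xlen_t>(h) * w * c * n);
  out.attr("dim") = IntegerVector::create(h, w, c, n);
  double* po = out.begin();
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        int col = s * h * w + j * h + i;
        const double* pc = &cols(0, col);
        for (int ch = 0; ch < c; ++ch) {
          double* base = po + ((size_t)s * c + ch) * h * w;
          for (int kj = 0; kj < k; ++kj) {
            int jj = j + kj - pad;
            if (jj < 0 || jj >= w) continue;
            for (int ki = 0; ki < k; ++ki) {
              int ii = i + ki - pad;
              if (ii < 0 || ii >= h) continue;
              base[jj * h + ii] += pc[ch * k * k + kj * k + ki];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  int oh = h / 2, ow = w / 2;
  NumericVector y(static_cast<R_xlen_t>(oh) * ow * c * n);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(oh, ow, c, n);
  const double* px = x.begin();
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      size_t off = ((size_t)s * c + ch) * h * w;
      size_t ooff = ((size_t)s * c + ch) * oh * ow;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double best = -DBL_MAX; size_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t ii = off + (size_t)(2 * j + dj) * h + (2 * i + di);
              if (px[ii] > best) { best = px[ii]; bidx = ii; }
            }
          y[ooff + (size_t)j * oh + i] = best;
          idx[ooff + (size_t)j * oh + i] = (int)(bidx + 1); // 1-based
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// bilinear resize with half-pixel centers; adjoint shares the weights
static void bilin_coef(int o, int in, int out, int& i0, int& i1, double& w1) {
  double src = (o + 0.5) * (double)in / out - 0.5;
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  i0 = (int)std::floor(src);
  i1 = i0 + 1 < in ? i0 + 1 : i0;
  w1 = src - i0;
}

// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int oh, int ow) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  NumericVector y(static_cast<R_xlen_t>(oh) * ow * c * n);
  y.attr("dim") = IntegerVector::create(oh, ow, c, n);
  const double* px = x.begin();
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double* b = px + ((size_t)s * c + ch) * h * w;
      double* py = y.begin() + ((size_t)s * c + ch) * oh * ow;
      for (int j = 0; j < ow; ++j) {
        int j0, j1; double wj;
        bilin_coef(j, w, ow, j0, j1, wj);
        for (int i = 0; i < oh; ++i) {
          int i0, i1; double wi;
          bilin_coef(i, h, oh, i0, i1, wi);
          py[(size_t)j * oh + i] =
            (1 - wi) * (1 - wj) * b[(size_t)j0 * h + i0] +
            wi * (1 - wj) * b[(size_t)j0 * h + i1] +
            (1 - wi) * wj * b[(size_t)j1 * h + i0] +
            wi * wj * b[(size_t)j1 * h + i1];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector dy, int h, int w) {
  IntegerVector d = dy.attr("dim");
  int oh = d[0], ow = d[1], c = d[2], n = d[3];
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      double* b = dx.begin() + ((size_t)s * c + ch) * h * w;
      const double* py = dy.begin() + ((size_t)s * c + ch) * oh * ow;
      for (int j = 0; j < ow; ++j) {
        int j0, j1; double wj;
        bilin_coef(j, w, ow, j0, j1, wj);
        for (int i = 0; i < oh; ++i) {
          int i0, i1; double wi;
          bilin_coef(i, h, oh, i0, i1, wi);
          double g = py[(size_t)j * oh + i];
          b[(size_t)j0 * h + i0] += (1 - wi) * (1 - wj) * g;
          b[(size_t)j0 * h + i1] += wi * (1 - wj) * g;
          b[(size_t)j1 * h + i0] += (1 - wi) * wj * g;
          b[(size_t)j1 * h + i1] += wi * wj * g;
        }
      }
    }
  return dx;
}

// depth-wise convolution with a per-sample, per-channel s x s kernel
// f: (h,w,c,n), k: (s,s,c,n), zero "same" padding
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector f, NumericVector kk) {
  IntegerVector df = f.attr("dim"), dk = kk.attr("dim");
  int h = df[0], w = df[1], c = df[2], n = df[3], s = dk[0];
  int pad = (s - 1) / 2;
  NumericVector y(f.size());
  y.attr("dim") = df;
  for (int b = 0; b < n; ++b)
    for (int ch = 0; ch < c; ++ch) {
      const double* pf = f.begin() + ((size_t)b * c + ch) * h * w;
      const double* pk = kk.begin() + ((size_t)b * c + ch) * s * s;
      double* py = y.begin() + ((size_t)b * c + ch) * h * w;
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          double acc = 0.0;
          for (int kj = 0; kj < s; ++kj) {
            int jj = j + kj - pad;
            if (jj < 0 || jj >= w) continue;
            for (int ki = 0; ki < s; ++ki) {
              int ii = i + ki - pad;
              if (ii < 0 || ii >= h) continue;
              acc += pf[(size_t)jj * h + ii] * pk[(size_t)kj * s + ki];
            }
          }
          py[(size_t)j * h + i] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_f_cpp(NumericVector dy, NumericVector kk) {
  IntegerVector dd = dy.attr("dim"), dk = kk.attr("dim");
  int h = dd[0], w = dd[1], c = dd[2], n = dd[3], s = dk[0];
  int pad = (s - 1) / 2;
  NumericVector dfv(dy.size());
  dfv.attr("dim") = dd;
  for (int b = 0; b < n; ++b)
    for (int ch = 0; ch < c; ++ch) {
      const double* pdy = dy.begin() + ((size_t)b * c + ch) * h * w;
      const double* pk = kk.begin() + ((size_t)b * c + ch) * s * s;
      double* pdf = dfv.begin() + ((size_t)b * c + ch) * h * w;
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          double g = pdy[(size_t)j * h + i];
          if (g == 0.0) continue;
          for (int kj = 0; kj < s; ++kj) {
            int jj = j + kj - pad;
            if (jj < 0 || jj >= w) continue;
            for (int ki = 0; ki < s; ++ki) {
              int ii = i + ki - pad;
              if (ii < 0 || ii >= h) continue;
              pdf[(size_t)jj * h + ii] += g * pk[(size_t)kj * s + ki];
            }
          }
        }
    }
  return dfv;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_k_cpp(NumericVector dy, NumericVector f, int s) {
  IntegerVector dd = dy.attr("dim");
  int h = dd[0], w = dd[1], c = dd[2], n = dd[3];
  int pad = (s - 1) / 2;
  NumericVector dkv(static_cast<R_xlen_t>(s) * s * c * n);
  dkv.attr("dim") = IntegerVector::create(s, s, c, n);
  for (int b = 0; b < n; ++b)
    for (int ch = 0; ch < c; ++ch) {
      const double* pdy = dy.begin() + ((size_t)b * c + ch) * h * w;
      const double* pf = f.begin() + ((size_t)b * c + ch) * h * w;
      double* pdk = dkv.begin() + ((size_t)b * c + ch) * s * s;
      for (int kj = 0; kj < s; ++kj)
        for (int ki = 0; ki < s; ++ki) {
          double acc = 0.0;
          for (int j = 0; j < w; ++j) {
            int jj = j + kj - pad;
            if (jj < 0 || jj >= w) continue;
            for (int i = 0; i < h; ++i) {
              int ii = i + ki - pad;
              if (ii < 0 || ii >= h) continue;
              acc += pdy[(size_t)j * h + i] * pf[(size_t)jj * h + ii];
            }
          }
          pdk[(size_t)kj * s + ki] = acc;
        }
    }
  return dkv;
}

// adaptive max pooling to s x s output (PyTorch-style window bounds)
// [[Rcpp::export]]
List adamaxpool_fwd_cpp(NumericVector x, int s) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  NumericVector y(static_cast<R_xlen_t>(s) * s * c * n);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(s, s, c, n);
  for (int b = 0; b < n; ++b)
    for (int ch = 0; ch < c; ++ch) {
      size_t off = ((size_t)b * c + ch) * h * w;
      size_t ooff = ((size_t)b * c + ch) * s * s;
      for (int j = 0; j < s; ++j) {
        int j0 = (int)std::floor((double)j * w / s);
        int j1 = (int)std::ceil((double)(j + 1) * w / s);
        for (int i = 0; i < s; ++i) {
          int i0 = (int)std::floor((double)i * h / s);
          int i1 = (int)std::ceil((double)(i + 1) * h / s);
          double best = -DBL_MAX; size_t bidx = 0;
          for (int jj = j0; jj < j1; ++jj)
            for (int ii = i0; ii < i1; ++ii) {
              size_t lin = off + (size_t)jj * h + ii;
              if (x[lin] > best) { best = x[lin]; bidx = lin; }
            }
          y[ooff + (size_t)j * s + i] = best;
          idx[ooff + (size_t)j * s + i] = (int)(bidx + 1);
        }
      }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector adamaxpool_bwd_cpp(NumericVector dy, IntegerVector idx,
                                 IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}
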