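// Convolution, pooling and im2col kernels for the internal NN engine.
// Activations are column-major R arrays: 1D data (channels x length),
// 3D data (channels x depth x height x width).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col1d(const arma::mat& x, int k, int stride, int pad) {
  const int ic = x.n_rows, len = x.n_cols;
  const int out_len = (len + 2 * pad - k) / stride + 1;
  arma::mat col(ic * k, out_len, arma::fill::zeros);
  for (int t = 0; t < out_len; ++t) {
    const int start = t * stride - pad;
    for (int kk = 0; kk < k; ++kk) {
      const int src = start + kk;
      if (src < 0 || src >= len) continue;
      for (int c = 0; c < ic; ++c) col(c * k + kk, t) = x(c, src);
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::mat& x, const arma::mat& W,
                     const arma::vec& b, int k, int stride, int pad) {
  arma::mat y = W * im2col1d(x, k, stride, pad);
  y.each_col() += b;
  return y;
}

// [[Rcpp::export]]
List conv1d_bwd(const arma::mat& x, const arma::mat& W, const arma::mat& dy,
                int k, int stride, int pad) {
  const int ic = x.n_rows, len = x.n_cols;
  arma::mat col = im2col1d(x, k, stride, pad);
  arma::mat dW = dy * col.t();
  arma::vec db = arma::sum(dy, 1);
  arma::mat dcol = W.t() * dy;
  arma::mat dx(ic, len, arma::fill::zeros);
  const int out_len = dy.n_cols;
  for (int t = 0; t < out_len; ++t) {
    const int start = t * stride - pad;
    for (int kk = 0; kk < k; ++kk) {
      const int src = start + kk;
      if (src < 0 || src >= len) continue;
      for (int c = 0; c < ic; ++c) dx(c, src) += dcol(c * k + kk, t);
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

static inline int idx4(int c, int d, int h, int w,
                       int nc, int nd, int nh) {
  return c + nc * (d + nd * (h + nh * w));
}

static void fill_col3d(const double* x, arma::mat& col, int od,
                       int ic, int D, int H,
                       int kd, int kh, int kw, int OH, int OW) {
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh) {
      const int j = oh + OH * ow;
      for (int ww = 0; ww < kw; ++ww)
        for (int hh = 0; hh < kh; ++hh)
          for (int dd = 0; dd < kd; ++dd) {
            const int base = ((0 * kd + dd) * kh + hh) * kw + ww;
            const double* src = x + idx4(0, od + dd, oh + hh, ow + ww,
                                         ic, D, H);
            for (int c = 0; c < ic; ++c)
              col(base + c * kd * kh * kw, j) = src[c];
          }
    }
}

// x dims (ic, D, H, W); W (oc x ic*kd*kh*kw); valid padding, stride 1.
// [[Rcpp::export]]
NumericVector conv3d_fwd(const NumericVector& x, const IntegerVector& xdim,
                         const arma::mat& W, const arma::vec& b,
                         int kd, int kh, int kw) {
  const int ic = xdim[0], D = xdim[1], H = xdim[2], Wd = xdim[3];
  const int oc = W.n_rows;
  const int OD = D - kd + 1, OH = H - kh + 1, OW = Wd - kw + 1;
  if (OD < 1 || OH < 1 || OW < 1)
    stop("conv3d: input (%d,%d,%d) smaller than kernel (%d,%d,%d)",
         D, H, Wd, kd, kh, kw);
  NumericVector y(static_cast<R_xlen_t>(oc) * OD * OH * OW);
  y.attr("dim") = IntegerVector::create(oc, OD, OH, OW);
  arma::mat col(ic * kd * kh * kw, OH * OW);
  double* yp = REAL(y);
  for (int od = 0; od < OD; ++od) {
    fill_col3d(REAL(const_cast<NumericVector&>(x)), col, od, ic, D, H,
               kd, kh, kw, OH, OW);
    arma::mat ys = W * col;   // oc x OH*OW
    ys.each_col() += b;
    for (int j = 0; j < OH * OW; ++j) {
      const int oh = j % OH, ow = j / OH;
      double* dst = yp + idx4(0, od, oh, ow, oc, OD, OH);
      for (int o = 0; o < oc; ++o) dst[o] = ys(o, j);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(const NumericVector& x, const IntegerVector& xdim,
                const arma::mat& W, const NumericVector& dy,
                int kd, int kh, int kw) {
  const int ic = xdim[0], D = xdim[1], H = xdim[2], Wd = xdim[3];
  const int oc = W.n_rows;
  const int OD = D - kd + 1, OH = H - kh + 1, OW = Wd - kw + 1;
  arma::mat dW(oc, ic * kd * kh * kw, arma::fill::zeros);
  arma::vec db(oc, arma::fill::zeros);
  NumericVector dx(static_cast<R_xlen_t>(ic) * D * H * Wd);
  dx.attr("dim") = xdim;
  arma::mat col(ic * kd * kh * kw, OH * OW);
  arma::mat dys(oc, OH * OW);
  const double* dyp = REAL(const_cast<NumericVector&>(dy));
  double* dxp = REAL(dx);
  for (int od = 0; od < OD; ++od) {
    fill_col3d(REAL(const_cast<NumericVector&>(x)), col, od, ic, D, H,
               kd, kh, kw, OH, OW);
    for (int j = 0; j < OH * OW; ++j) {
      const int oh = j % OH, ow = j / OH;
      const double* src = dyp + idx4(0, od, oh, ow, oc, OD, OH);
      for (int o = 0; o < oc; ++o) dys(o, j) = src[o];
    }
    dW += dys * col.t();
    db += arma::sum(dys, 1);
    arma::mat dcol = W.t() * dys;  // (ic*kd*kh*kw) x OH*OW
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const int j = oh + OH * ow;
        for (int ww = 0; ww < kw; ++ww)
          for (int hh = 0; hh < kh; ++hh)
            for (int dd = 0; dd < kd; ++dd) {
              double* dst = dxp + idx4(0, od + dd, oh + hh, ow + ww,
                                       ic, D, H);
              const int base = (dd * kh + hh) * kw + ww;
              for (int c = 0; c < ic; ++c)
                dst[c] += dcol(base + c * kd * kh * kw, j);
            }
      }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// max pooling, kernel == stride, valid; returns values and argmax indices
// [[Rcpp::export]]
List maxpool3d_fwd(const NumericVector& x, const IntegerVector& xdim,
                   int kd, int kh, int kw) {
  const int ic = xdim[0], D = xdim[1], H = xdim[2], Wd = xdim[3];
  const int OD = D / kd, OH = H / kh, OW = Wd / kw;
  if (OD < 1 || OH < 1 || OW < 1) stop("maxpool3d: input smaller than kernel");
  NumericVector y(static_cast<R_xlen_t>(ic) * OD * OH * OW);
  IntegerVector amax(y.size());
  y.attr("dim") = IntegerVector::create(ic, OD, OH, OW);
  const double* xp = REAL(const_cast<NumericVector&>(x));
  double* yp = REAL(y);
  int* ap = INTEGER(amax);
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int od = 0; od < OD; ++od)
        for (int c = 0; c < ic; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int ww = 0; ww < kw; ++ww)
            for (int hh = 0; hh < kh; ++hh)
              for (int dd = 0; dd < kd; ++dd) {
                const int i = idx4(c, od * kd + dd, oh * kh + hh,
                                   ow * kw + ww, ic, D, H);
                if (xp[i] > best) { best = xp[i]; besti = i; }
              }
          const int o = idx4(c, od, oh, ow, ic, OD, OH);
          yp[o] = best;
          ap[o] = besti;
        }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(const NumericVector& dy, const IntegerVector& argmax,
                            const IntegerVector& xdim) {
  R_xlen_t n = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = REAL(dx);
  const double* dyp = REAL(const_cast<NumericVector&>(dy));
  const int* ap = INTEGER(const_cast<IntegerVector&>(argmax));
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ap[i]] += dyp[i];
  return dx;
}

// elementwise PReLU with per-channel slope recycling over dim 1
// [[Rcpp::export]]
NumericVector prelu_fwd_cpp(const NumericVector& x, const NumericVector& a) {
  const R_xlen_t n = x.size();
  const int C = a.size();
  NumericVector y(n);
  if (x.hasAttribute("dim")) y.attr("dim") = x.attr("dim");
  const double* xp = REAL(const_cast<NumericVector&>(x));
  const double* ap = REAL(const_cast<NumericVector&>(a));
  double* yp = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = xp[i];
    yp[i] = v > 0 ? v : ap[i % C] * v;
  }
  return y;
}

// per-channel affine y = a[c] * x + b[c] (evaluation-mode batch norm)
// [[Rcpp::export]]
NumericVector channel_affine_cpp(const NumericVector& x, const NumericVector& a,
                                 const NumericVector& b) {
  const R_xlen_t n = x.size();
  const int C = a.size();
  NumericVector y(n);
  if (x.hasAttribute("dim")) y.attr("dim") = x.attr("dim");
  const double* xp = REAL(const_cast<NumericVector&>(x));
  const double* ap = REAL(const_cast<NumericVector&>(a));
  const double* bp = REAL(const_cast<NumericVector&>(b));
  double* yp = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int c = i % C;
    yp[i] = ap[c] * xp[i] + bp[c];
  }
  return y;
}
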