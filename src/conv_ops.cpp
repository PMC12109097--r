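// Minimal 2D convolution kernels for the segmentation backbone.
// Layout is R column-major throughout: images (H, W, C, N), kernels
// (k, k, Cin, Cout). Same-padding with zeros, stride 1, odd k only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int Cin, int k, int pad,
                   arma::mat& X) {
  // X is (H*W) x (k*k*Cin); row r = i + H*j for output pixel (i, j)
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        double* Xcol = X.colptr(col);
        for (int j = 0; j < W; ++j) {
          int jj = j + kw - pad;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) Xcol[i + (size_t)H * j] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            int ii = i + kh - pad;
            Xcol[i + (size_t)H * j] = (ii < 0 || ii >= H) ? 0.0 : src[ii];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int pad = (k - 1) / 2;
  if (wd[1] != k || wd[2] != Cin) stop("kernel/input channel mismatch");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  arma::mat X(H * W, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, pad, X);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n, H * W, Cout, false,
                true);
    Y = X * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int pad = (k - 1) / 2;

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);

  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat dWm(dw.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);

  arma::mat X(H * W, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, pad, X);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                 H * W, Cout, false, true);
    dWm += X.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dX = dY * Wm.t();  // (H*W) x (k*k*Cin)
    // col2im scatter-add
    double* dxn = dx.begin() + (size_t)H * W * Cin * n;
    for (int c = 0; c < Cin; ++c) {
      double* dxc = dxn + (size_t)H * W * c;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          int col = kh + k * kw + k * k * c;
          const double* dXcol = dX.colptr(col);
          for (int j = 0; j < W; ++j) {
            int jj = j + kw - pad;
            if (jj < 0 || jj >= W) continue;
            double* dst = dxc + (size_t)H * jj;
            for (int i = 0; i < H; ++i) {
              int ii = i + kh - pad;
              if (ii >= 0 && ii < H) dst[ii] += dXcol[i + (size_t)H * j];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
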