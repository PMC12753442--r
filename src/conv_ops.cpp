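// Low-level 2-D convolution and max-pooling kernels for the image encoders.
// Layout convention: image batches are R arrays dim (H, W, C, N), weights
// dim (kh, kw, Cin, Cout), both column-major. im2col turns each sample into
// a (kh*kw*Cin) x (Ho*Wo) matrix so the convolution is a single GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  // col is K x P with K = kh*kw*C, P = Ho*Wo; row r = ki + kh*(kj + kw*c)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * stride + kj - pad;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride + ki - pad;
            double v = 0.0;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W)
              v = xc[ii + (size_t)H * jj];
            col(r, oi + Ho * oj) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            xc[ii + (size_t)H * jj] += col(r, oi + Ho * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d_fwd: channel mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d_fwd: kernel larger than padded input");
  int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wmat(w.begin(), K, Co, false);  // K x Co view, no copy
  NumericVector y = make4d(Ho, Wo, Co, N);
  arma::mat col(K, P);
  for (int s = 0; s < N; ++s) {
    im2col(x.begin() + (size_t)H * W * C * s, H, W, C, kh, kw,
           stride, pad, Ho, Wo, col);
    arma::mat Y = col.t() * Wmat;  // P x Co, matches (Ho,Wo,Co) col-major
    double* ys = y.begin() + (size_t)P * Co * s;
    for (int o = 0; o < Co; ++o) {
      double bo = b[o];
      for (int p = 0; p < P; ++p) ys[p + (size_t)P * o] = Y(p, o) + bo;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wmat(w.begin(), K, Co, false);
  NumericVector dx = make4d(H, W, C, N);
  NumericVector dw = make4d(kh, kw, C, Co);
  NumericVector db(Co);
  arma::mat dWmat(dw.begin(), K, Co, false);
  arma::mat col(K, P);
  for (int s = 0; s < N; ++s) {
    im2col(x.begin() + (size_t)H * W * C * s, H, W, C, kh, kw,
           stride, pad, Ho, Wo, col);
    const double* dys = dy.begin() + (size_t)P * Co * s;
    arma::mat dY(const_cast<double*>(dys), P, Co, false);  // P x Co view
    dWmat += col * dY;
    for (int o = 0; o < Co; ++o)
      db[o] += arma::accu(dY.col(o));
    arma::mat dcol = Wmat * dY.t();  // K x P
    col2im_add(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
               dx.begin() + (size_t)H * W * C * s);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("maxpool_fwd: window larger than input");
  NumericVector y = make4d(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x of each max
  size_t q = 0;
  for (int s = 0; s < N; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * s);
      size_t base = (size_t)H * W * (c + (size_t)C * s);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -INFINITY;
          size_t bestix = 0;
          for (int kj = 0; kj < k; ++kj) {
            for (int ki = 0; ki < k; ++ki) {
              int ii = oi * stride + ki, jj = oj * stride + kj;
              double v = xc[ii + (size_t)H * jj];
              if (v > best) { best = v; bestix = ii + (size_t)H * jj; }
            }
          }
          // y is filled in its own column-major order as (oi, oj, c, s) nests
          y[oi + (size_t)Ho * (oj + (size_t)Wo * (c + (size_t)C * s))] = best;
          idx[oi + (size_t)Ho * (oj + (size_t)Wo * (c + (size_t)C * s))] =
            (int)(base + bestix);
          (void)q;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(IntegerVector xdim, IntegerVector idx,
                          NumericVector dy) {
  NumericVector dx = make4d(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}
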