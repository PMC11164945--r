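// Minimal conv-net kernels: 3x3 same-padding convolution and 2x2 max pooling,
// forward and backward, over batches stored as H x W x C x N arrays.
// Dense layers, activations and the optimizer live in R; only the
// convolution/pooling inner loops are compiled.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// column layout: c * 9 + (dj + 1) * 3 + (di + 1); must match conv weight rows
static void im2col3(const double* x, int H, int W, int C, arma::mat& M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        double* m = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const double* src = xc + (size_t)js * H;
          double* dst = m + (size_t)j * H;
          const int i0 = (di < 0) ? 1 : 0;
          const int i1 = (di > 0) ? H - 1 : H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
}

static void col2im3(const arma::mat& M, int H, int W, int C, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* m = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          double* dst = xc + (size_t)js * H;
          const double* src = m + (size_t)j * H;
          const int i0 = (di < 0) ? 1 : 0;
          const int i1 = (di > 0) ? H - 1 : H;
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.ncol();
  if (w.nrow() != 9 * C) stop("conv weight rows must equal 9 * channels");
  if (b.size() != F) stop("conv bias length must equal filter count");
  NumericVector out((R_xlen_t)H * W * F * N);
  out.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat Wm(w.begin(), 9 * C, F, false, true);
  arma::rowvec bv(b.begin(), F);
  arma::mat M(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)n * H * W * C, H, W, C, M);
    arma::mat Y = M * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)n * H * W * F);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.ncol();
  IntegerVector dd = dims4(dy);
  if (dd[0] != H || dd[1] != W || dd[2] != F || dd[3] != N)
    stop("dy dims do not match conv output");
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat Wm(w.begin(), 9 * C, F, false, true);
  arma::mat dW(9 * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  arma::mat M(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)n * H * W * C, H, W, C, M);
    arma::mat dY(dy.begin() + (size_t)n * H * W * F, H * W, F, false, true);
    dW += M.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();
    col2im3(dM, H, W, C, dx.begin() + (size_t)n * H * W * C);
  }
  NumericMatrix dWr(9 * C, F);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(F);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("pooling requires even height and width");
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx((R_xlen_t)H2 * W2 * C * N);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * H * W;
      double* ys = y.begin() + ((size_t)n * C + c) * H2 * W2;
      int* is = idx.begin() + ((size_t)n * C + c) * H2 * W2;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i) {
          int best = (2 * i) + (2 * j) * H;
          double bv = xs[best];
          const int cand[3] = {2 * i + 1 + 2 * j * H,
                               2 * i + (2 * j + 1) * H,
                               2 * i + 1 + (2 * j + 1) * H};
          for (int k = 0; k < 3; ++k)
            if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
          ys[i + j * H2] = bv;
          is[i + j * H2] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dims4(dy);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  if (H2 * 2 != H || W2 * 2 != W) stop("pooled dims do not match H, W");
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* ds = dy.begin() + ((size_t)n * C + c) * H2 * W2;
      const int* is = idx.begin() + ((size_t)n * C + c) * H2 * W2;
      double* xs = dx.begin() + ((size_t)n * C + c) * H * W;
      const int m = H2 * W2;
      for (int k = 0; k < m; ++k) xs[is[k]] += ds[k];
    }
  }
  return dx;
}
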