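// Convolution and pooling primitives for the fusion network.
//
// Layout: activations are arma::cube (H, W, C); a conv layer's weights are a
// matrix (C_out, k*k*C_in) whose columns follow im2col patch order (row
// offset fastest, then column offset, then input channel). Same-size zero
// padding, stride 1, odd k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  const int nrowA = k * k * C;
  mat A(nrowA, H * W, fill::zeros);
  double* Ap = A.memptr();
  const double* xp = x.memptr();
  for (int c = 0; c < C; ++c) {
    const double* s = xp + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int rowA = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i_lo = std::max(0, p - di);
          const int i_hi = std::min(H, H + p - di);
          const double* src = s + (std::size_t)sj * H + (i_lo + di - p);
          double* dst = Ap + (std::size_t)(i_lo + (std::size_t)j * H) * nrowA + rowA;
          for (int i = i_lo; i < i_hi; ++i) {
            *dst = *src++;
            dst += nrowA;
          }
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& w,
                    const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat A = im2col(x, k);
  mat Y = w * A;            // (Cout, H*W)
  Y.each_col() += b;
  cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c) {
    y.slice(c) = reshape(Y.row(c), H, W);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  const int p = k / 2;
  mat A = im2col(x, k);
  mat dY(Cout, H * W);
  for (int c = 0; c < Cout; ++c) {
    dY.row(c) = vectorise(dy.slice(c)).t();
  }
  mat dw = dY * A.t();
  vec db = sum(dY, 1);
  mat dA = w.t() * dY;      // (k*k*Cin, H*W)
  const int nrowA = dA.n_rows;
  const double* dAp = dA.memptr();
  cube dx(H, W, Cin, fill::zeros);
  double* dxp = dx.memptr();
  for (int c = 0; c < Cin; ++c) {
    double* s = dxp + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int rowA = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i_lo = std::max(0, p - di);
          const int i_hi = std::min(H, H + p - di);
          double* dst = s + (std::size_t)sj * H + (i_lo + di - p);
          const double* src = dAp + (std::size_t)(i_lo + (std::size_t)j * H) * nrowA + rowA;
          for (int i = i_lo; i < i_hi; ++i) {
            *dst++ += *src;
            src += nrowA;
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pool, stride 2. Returns pooled cube and the flat argmax index
// (0-based, within the input cube) per output element.
// [[Rcpp::export]]
Rcpp::List maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = x(i0, j0, c);
        int bi = i0, bj = j0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(i0 + di, j0 + dj, c);
            if (v > best) { best = v; bi = i0 + di; bj = j0 + dj; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = (uword)(bi + bj * H + c * H * W);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd(const arma::ucube& idx, const arma::cube& dy,
                       const int H, const int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const uword n = idx.n_elem;
  for (uword e = 0; e < n; ++e) {
    dx(idx(e)) += dy(e);
  }
  return dx;
}
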