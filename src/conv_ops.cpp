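// Convolution and pooling kernels for the dual-branch classifier.
//
// Batched activations are stored as arma::cube(H, W, C * N): slice
// (n-1)*C + c holds channel c of sample n.  Convolutions use im2col and a
// single BLAS GEMM per sample; kernels are fixed at 3x3 (2-D) and 3 (1-D)
// with stride 1 and zero padding 1, the configuration the network uses
// everywhere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gather a (Cin*9) x (H*W) patch matrix for one sample, zero-padded borders.
static void im2col3(const cube& x, uword n, uword cin, mat& K) {
  const uword H = x.n_rows, W = x.n_cols;
  K.zeros();
  for (uword c = 0; c < cin; ++c) {
    const mat& xc = x.slice(n * cin + c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        uword row = c * 9 + (uword)((dy + 1) * 3 + (dx + 1));
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            int is = (int)i + dy;
            if (is < 0 || is >= (int)H) continue;
            K(row, j * H + i) = xc((uword)is, (uword)js);
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col3: accumulate patch-matrix gradients back
// onto the padded input grid.
static void col2im3(const mat& G, uword cin, uword H, uword W, cube& dx,
                    uword n) {
  for (uword c = 0; c < cin; ++c) {
    mat& dxc = dx.slice(n * cin + c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        uword row = c * 9 + (uword)((dy + 1) * 3 + (dx_ + 1));
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dx_;
          if (js < 0 || js >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            int is = (int)i + dy;
            if (is < 0 || is >= (int)H) continue;
            dxc((uword)is, (uword)js) += G(row, j * H + i);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int n_samples) {
  const uword N = (uword)n_samples;
  const uword H = x.n_rows, W = x.n_cols;
  const uword cin = x.n_slices / N, cout = w.n_rows;
  cube y(H, W, cout * N);
  mat K(cin * 9, H * W);
  for (uword n = 0; n < N; ++n) {
    im2col3(x, n, cin, K);
    mat Y = w * K;              // cout x (H*W)
    Y.each_col() += b;
    for (uword c = 0; c < cout; ++c)
      y.slice(n * cout + c) = reshape(Y.row(c), H, W);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gy, int n_samples) {
  const uword N = (uword)n_samples;
  const uword H = x.n_rows, W = x.n_cols;
  const uword cin = x.n_slices / N, cout = w.n_rows;
  cube dx(H, W, cin * N, fill::zeros);
  mat dw(w.n_rows, w.n_cols, fill::zeros);
  vec db(cout, fill::zeros);
  mat K(cin * 9, H * W), GY(cout, H * W);
  for (uword n = 0; n < N; ++n) {
    im2col3(x, n, cin, K);
    for (uword c = 0; c < cout; ++c) {
      GY.row(c) = vectorise(gy.slice(n * cout + c)).t();
      db(c) += accu(gy.slice(n * cout + c));
    }
    dw += GY * K.t();
    mat G = w.t() * GY;         // (cin*9) x (H*W)
    col2im3(G, cin, H, W, dx, n);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2 (floor of odd trailing edge).
// [[Rcpp::export]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, S = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, S);
  ucube idx(Ho, Wo, S);         // linear index into the input slice
  for (uword s = 0; s < S; ++s) {
    const mat& xs = x.slice(s);
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        uword bi = 2 * i, bj = 2 * j;
        double best = xs(bi, bj);
        uword besti = bj * H + bi;
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di) {
            double v = xs(bi + di, bj + dj);
            if (v > best) { best = v; besti = (bj + dj) * H + bi + di; }
          }
        y(i, j, s) = best;
        idx(i, j, s) = besti;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& gy, const arma::ucube& idx, int H,
                       int W) {
  const uword S = gy.n_slices;
  cube dx((uword)H, (uword)W, S, fill::zeros);
  for (uword s = 0; s < S; ++s) {
    mat& d = dx.slice(s);
    const mat& g = gy.slice(s);
    const umat& id = idx.slice(s);
    for (uword j = 0; j < gy.n_cols; ++j)
      for (uword i = 0; i < gy.n_rows; ++i) d(id(i, j)) += g(i, j);
  }
  return dx;
}

// 1-D convolution over a length-L sequence batch stored as mat(L, C*N),
// kernel 3, stride 1, zero padding 1.
static void seq_im2col3(const mat& x, uword n, uword cin, mat& K) {
  const uword L = x.n_rows;
  K.zeros();
  for (uword c = 0; c < cin; ++c) {
    const vec xc = x.col(n * cin + c);
    for (int d = -1; d <= 1; ++d) {
      uword row = c * 3 + (uword)(d + 1);
      for (uword p = 0; p < L; ++p) {
        int ps = (int)p + d;
        if (ps < 0 || ps >= (int)L) continue;
        K(row, p) = xc((uword)ps);
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv1d_fw(const arma::mat& x, const arma::mat& w, const arma::vec& b,
                    int n_samples) {
  const uword N = (uword)n_samples, L = x.n_rows;
  const uword cin = x.n_cols / N, cout = w.n_rows;
  mat y(L, cout * N);
  mat K(cin * 3, L);
  for (uword n = 0; n < N; ++n) {
    seq_im2col3(x, n, cin, K);
    mat Y = w * K;
    Y.each_col() += b;
    for (uword c = 0; c < cout; ++c) y.col(n * cout + c) = Y.row(c).t();
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bw(const arma::mat& x, const arma::mat& w,
                     const arma::mat& gy, int n_samples) {
  const uword N = (uword)n_samples, L = x.n_rows;
  const uword cin = x.n_cols / N, cout = w.n_rows;
  mat dx(L, cin * N, fill::zeros);
  mat dw(w.n_rows, w.n_cols, fill::zeros);
  vec db(cout, fill::zeros);
  mat K(cin * 3, L), GY(cout, L);
  for (uword n = 0; n < N; ++n) {
    seq_im2col3(x, n, cin, K);
    for (uword c = 0; c < cout; ++c) {
      GY.row(c) = gy.col(n * cout + c).t();
      db(c) += accu(gy.col(n * cout + c));
    }
    dw += GY * K.t();
    mat G = w.t() * GY;         // (cin*3) x L
    for (uword c = 0; c < cin; ++c) {
      vec acc(L, fill::zeros);
      for (int d = -1; d <= 1; ++d) {
        uword row = c * 3 + (uword)(d + 1);
        for (uword p = 0; p < L; ++p) {
          int ps = (int)p + d;
          if (ps < 0 || ps >= (int)L) continue;
          acc((uword)ps) += G(row, p);
        }
      }
      dx.col(n * cin + c) += acc;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
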