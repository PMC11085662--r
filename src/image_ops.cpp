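// Classic image-processing primitives used by the enhancement stage:
// Gaussian smoothing, Sobel gradients, non-maximum suppression and
// hysteresis linking (Canny-style edge detection).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat gaussian_kernel1d(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  k /= accu(k);
  return k;
}

// Separable Gaussian blur with edge replication.
// [[Rcpp::export]]
arma::mat gaussian_blur(const arma::mat& x, double sigma) {
  if (sigma <= 0) return x;
  mat k = gaussian_kernel1d(sigma);
  int r = ((int)k.n_rows - 1) / 2;
  const int H = (int)x.n_rows, W = (int)x.n_cols;
  mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = -r; d <= r; ++d) {
        int ii = std::min(std::max(i + d, 0), H - 1);
        s += k(d + r) * x(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = -r; d <= r; ++d) {
        int jj = std::min(std::max(j + d, 0), W - 1);
        s += k(d + r) * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// [[Rcpp::export]]
arma::mat canny_edges(const arma::mat& img, double sigma, double low,
                      double high) {
  const int H = (int)img.n_rows, W = (int)img.n_cols;
  mat x = gaussian_blur(img, sigma);
  mat gx(H, W, fill::zeros), gy(H, W, fill::zeros), mag(H, W, fill::zeros);
  for (int j = 1; j < W - 1; ++j)
    for (int i = 1; i < H - 1; ++i) {
      gx(i, j) = (x(i - 1, j + 1) + 2 * x(i, j + 1) + x(i + 1, j + 1)) -
                 (x(i - 1, j - 1) + 2 * x(i, j - 1) + x(i + 1, j - 1));
      gy(i, j) = (x(i + 1, j - 1) + 2 * x(i + 1, j) + x(i + 1, j + 1)) -
                 (x(i - 1, j - 1) + 2 * x(i - 1, j) + x(i - 1, j + 1));
      mag(i, j) = std::sqrt(gx(i, j) * gx(i, j) + gy(i, j) * gy(i, j));
    }
  // non-maximum suppression along the quantized gradient direction
  mat thin(H, W, fill::zeros);
  for (int j = 1; j < W - 1; ++j)
    for (int i = 1; i < H - 1; ++i) {
      double m = mag(i, j);
      if (m <= 0) continue;
      double ang = std::atan2(gy(i, j), gx(i, j)) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      double a, b;
      if (ang < 22.5 || ang >= 157.5) { a = mag(i, j - 1); b = mag(i, j + 1); }
      else if (ang < 67.5) { a = mag(i - 1, j - 1); b = mag(i + 1, j + 1); }
      else if (ang < 112.5) { a = mag(i - 1, j); b = mag(i + 1, j); }
      else { a = mag(i - 1, j + 1); b = mag(i + 1, j - 1); }
      if (m >= a && m >= b) thin(i, j) = m;
    }
  // hysteresis: keep weak pixels 8-connected to a strong pixel
  mat out(H, W, fill::zeros);
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (thin(i, j) >= high) { out(i, j) = 1; q.push({i, j}); }
  while (!q.empty()) {
    auto [i, j] = q.front();
    q.pop();
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int ii = i + di, jj = j + dj;
        if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
        if (out(ii, jj) == 0 && thin(ii, jj) >= low) {
          out(ii, jj) = 1;
          q.push({ii, jj});
        }
      }
  }
  return out;
}
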