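// Low-level array kernels for the convolutional networks and image warping.
// All image/feature arrays use the R layout dim = c(H, W, C), column-major,
// so slice c of an arma::cube maps onto image channel c with (row = y, col = x).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding 1. Output: (9*C) x (H*W),
// column j*H + i holds the unrolled receptive field of pixel (i, j).
static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(9 * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int r = c * 9 + (dx + 1) * 3 + (dy + 1);
        const int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc.colptr(j + dx) + (i0 + dy);
          double* dst = col.colptr(0) + r;  // stride 9*C between pixels
          for (int i = i0; i < i1; ++i)
            dst[(size_t)(j * H + i) * (9 * C)] = src[i - i0];
        }
      }
    }
  }
  return col;
}

// Scatter-add transpose of im2col3.
static arma::cube col2im3(const arma::mat& col, int H, int W, int C) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& xc = x.slice(c);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int r = c * 9 + (dx + 1) * 3 + (dy + 1);
        const int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j) {
          double* dst = xc.colptr(j + dx) + (i0 + dy);
          const double* src = col.colptr(0) + r;
          for (int i = i0; i < i1; ++i)
            dst[i - i0] += src[(size_t)(j * H + i) * (9 * C)];
        }
      }
    }
  }
  return x;
}

static arma::mat y_to_mat(const arma::cube& dy) {
  // (H,W,Cout) -> (Cout x H*W)
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  arma::mat m(C, H * W);
  for (int c = 0; c < C; ++c)
    m.row(c) = arma::vectorise(dy.slice(c)).t();
  return m;
}

static arma::cube mat_to_y(const arma::mat& m, int H, int W) {
  arma::cube y(H, W, m.n_rows);
  for (unsigned c = 0; c < m.n_rows; ++c)
    y.slice(c) = arma::reshape(m.row(c).t(), H, W);
  return y;
}

// 3x3 convolution, zero padding 1. w: Cout x (9*Cin), b: Cout.
// [[Rcpp::export]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b) {
  arma::mat col = im2col3(x);
  arma::mat y = w * col;
  y.each_col() += b;
  return mat_to_y(y, x.n_rows, x.n_cols);
}

// Backward pass; returns dx, dw, db.
// [[Rcpp::export]]
List conv3_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy) {
  arma::mat col = im2col3(x);
  arma::mat dym = y_to_mat(dy);
  arma::mat dw = dym * col.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dcol = w.t() * dym;
  arma::cube dx = col2im3(dcol, x.n_rows, x.n_cols, x.n_slices);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 1x1 convolution (pixelwise linear map). w: Cout x Cin.
// [[Rcpp::export]]
arma::cube conv1_fwd(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat xm(C, H * W);
  for (int c = 0; c < C; ++c) xm.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat y = w * xm;
  y.each_col() += b;
  return mat_to_y(y, H, W);
}

// [[Rcpp::export]]
List conv1_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat xm(C, H * W);
  for (int c = 0; c < C; ++c) xm.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat dym = y_to_mat(dy);
  arma::mat dw = dym * xm.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dxm = w.t() * dym;
  return List::create(_["dx"] = mat_to_y(dxm, H, W), _["dw"] = dw,
                      _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled cube and 1-based argmax linear
// indices (into each input slice) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = xc(2 * i, 2 * j);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            if (xc(2 * i + di, 2 * j + dj) > best) {
              best = xc(2 * i + di, 2 * j + dj);
              bi = 2 * i + di; bj = 2 * j + dj;
            }
        y(i, j, c) = best;
        idx(i, j, c) = (unsigned)(bj * H + bi + 1);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& dy,
                        int H, int W) {
  const int C = dy.n_slices, Ho = dy.n_rows, Wo = dy.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& dxc = dx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dxc(idx(i, j, c) - 1) += dy(i, j, c);
  }
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;       y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;   y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// Bilinear resampling of all channels at source coordinates (map_y, map_x),
// 0-based pixel indices; samples falling outside the frame read as 0.
// out(i, j, c) = x(map_y(i, j), map_x(i, j), c) interpolated.
// [[Rcpp::export]]
arma::cube bilinear_warp(const arma::cube& x, const arma::mat& map_y,
                         const arma::mat& map_x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = map_y.n_rows, Wo = map_y.n_cols;
  arma::cube out(Ho, Wo, C, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double sy = map_y(i, j), sx = map_x(i, j);
      const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      const double fy = sy - y0, fx = sx - x0;
      for (int c = 0; c < C; ++c) {
        double acc = 0.0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int yy = y0 + di, xx = x0 + dj;
            if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
            const double wgt = (di ? fy : 1 - fy) * (dj ? fx : 1 - fx);
            if (wgt != 0.0) acc += wgt * x(yy, xx, c);
          }
        }
        out(i, j, c) = acc;
      }
    }
  }
  return out;
}
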