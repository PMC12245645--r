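// Monolithic forward/backward pass of the U-Net so one training step costs
// a single R->C++ round trip. Mirrors the layer layout documented in
// R/localization.R: per level two 3x3 conv + ReLU blocks; 2x2 max-pool down
// with dropout after each pool; nearest-neighbour 2x upsampling with dropout
// after each upsample, skip concatenation, and a linear 1x1 output head.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transposed im2col for 3x3 / pad 1: (H*W) x (9*C); row j*H+i holds the
// receptive field of pixel (i, j). Contiguous column writes keep this
// memory-bound step cache-friendly.
static arma::mat im2colT(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        const int r = c * 9 + (dx + 1) * 3 + (dy + 1);
        double* dst = col.colptr(r);
        const int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc.colptr(j + dx) + i0 + dy;
          std::copy(src, src + (i1 - i0), dst + (size_t)j * H + i0);
        }
      }
  }
  return col;
}

static arma::cube col2imT(const arma::mat& col, int H, int W, int C) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& xc = x.slice(c);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        const int r = c * 9 + (dx + 1) * 3 + (dy + 1);
        const double* src = col.colptr(r);
        const int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j) {
          double* dst = xc.colptr(j + dx) + i0 + dy;
          const double* s = src + (size_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += s[i];
        }
      }
  }
  return x;
}

static arma::cube mat_to_cube(const arma::mat& m, int H, int W) {
  // columns of m (H*W x C) become slices
  arma::cube y(H, W, m.n_cols);
  std::copy(m.memptr(), m.memptr() + m.n_elem, y.memptr());
  return y;
}

static arma::mat cube_to_mat(const arma::cube& x) {
  arma::mat m(x.n_rows * x.n_cols, x.n_slices);
  std::copy(x.memptr(), x.memptr() + x.n_elem, m.memptr());
  return m;
}

struct ConvCache {
  arma::mat col;   // im2colT of the input
  arma::cube out;  // post-ReLU output
  int H, W, C_in;
};

// y = leaky_relu(conv3(x, W, b)); caches col and the activated output.
// Leaky slope 0.01 keeps gradients alive when a unit's input goes negative.
static arma::cube conv_relu(const arma::cube& x, const arma::mat& Wt,
                            const arma::vec& b, ConvCache& cc) {
  cc.col = im2colT(x);
  cc.H = x.n_rows; cc.W = x.n_cols; cc.C_in = x.n_slices;
  arma::mat y = cc.col * Wt.t();
  y.each_row() += b.t();
  y.transform([](double v) { return v > 0 ? v : 0.01 * v; });
  cc.out = mat_to_cube(y, x.n_rows, x.n_cols);
  return cc.out;
}

// Backward through ReLU + conv3 given the cached col/out.
static arma::cube conv_relu_bwd(const ConvCache& cc, const arma::mat& Wt,
                                arma::cube dy, arma::mat& dW, arma::vec& db) {
  // leaky-ReLU gate
  const double* o = cc.out.memptr();
  double* d = dy.memptr();
  for (size_t i = 0; i < dy.n_elem; ++i) if (o[i] <= 0) d[i] *= 0.01;
  arma::mat dym = cube_to_mat(dy);            // HW x Cout
  dW = dym.t() * cc.col;                      // Cout x 9Cin
  db = arma::sum(dym, 0).t();
  arma::mat dcol = dym * Wt;                  // HW x 9Cin
  return col2imT(dcol, cc.H, cc.W, cc.C_in);
}

struct PoolCache { arma::ucube idx; int H, W; };

static arma::cube pool2(const arma::cube& x, PoolCache& pc) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  pc.H = H; pc.W = W;
  pc.idx.set_size(Ho, Wo, C);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = xc(bi, bj);
        if (xc(bi + 1, bj) > best) { best = xc(bi + 1, bj); bi++; }
        if (xc(2 * i, bj + 1) > best) { best = xc(2 * i, bj + 1); bi = 2 * i; bj++; }
        if (xc(2 * i + 1, 2 * j + 1) > best) { best = xc(2 * i + 1, 2 * j + 1); bi = 2 * i + 1; bj = 2 * j + 1; }
        y(i, j, c) = best;
        pc.idx(i, j, c) = (unsigned)(bj * H + bi);
      }
  }
  return y;
}

static arma::cube pool2_bwd(const PoolCache& pc, const arma::cube& dy) {
  arma::cube dx(pc.H, pc.W, dy.n_slices, arma::fill::zeros);
  for (unsigned c = 0; c < dy.n_slices; ++c) {
    arma::mat& dxc = dx.slice(c);
    for (unsigned j = 0; j < dy.n_cols; ++j)
      for (unsigned i = 0; i < dy.n_rows; ++i)
        dxc(pc.idx(i, j, c)) += dy(i, j, c);
  }
  return dx;
}

static arma::cube up2(const arma::cube& x) {
  arma::cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (unsigned c = 0; c < x.n_slices; ++c)
    for (unsigned j = 0; j < x.n_cols; ++j)
      for (unsigned i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

static arma::cube up2_bwd(const arma::cube& dy) {
  arma::cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (unsigned c = 0; c < dx.n_slices; ++c)
    for (unsigned j = 0; j < dx.n_cols; ++j)
      for (unsigned i = 0; i < dx.n_rows; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

struct BlockP { arma::mat W1, W2; arma::vec b1, b2; };

static BlockP read_block(const List& blk) {
  List c1 = blk["c1"], c2 = blk["c2"];
  BlockP p;
  p.W1 = as<arma::mat>(c1["W"]); p.b1 = as<arma::vec>(c1["b"]);
  p.W2 = as<arma::mat>(c2["W"]); p.b2 = as<arma::vec>(c2["b"]);
  return p;
}

// Full forward (and optional backward) pass. params is the R parameter
// list (enc / dec / out); masks a list of dropout-mask cubes in the order
// pools-then-upsamples, or an empty list to disable dropout. When target
// has size 0 only the forward output is returned.
// [[Rcpp::export]]
List unet_run(const List& params, const arma::cube& x, const List& masks,
              const arma::mat& target, bool want_grad) {
  List enc_l = params["enc"], dec_l = params["dec"], out_l = params["out"];
  const int L = enc_l.size();
  const bool use_masks = masks.size() > 0;
  std::vector<arma::cube> mask(use_masks ? masks.size() : 0);
  if (use_masks)
    for (int i = 0; i < masks.size(); ++i) mask[i] = as<arma::cube>(masks[i]);

  std::vector<BlockP> enc(L), dec(L - 1);
  for (int l = 0; l < L; ++l) enc[l] = read_block(enc_l[l]);
  for (int l = 0; l < L - 1; ++l) dec[l] = read_block(dec_l[l]);
  arma::mat outW = as<arma::mat>(out_l["W"]);
  arma::vec outb = as<arma::vec>(out_l["b"]);

  std::vector<ConvCache> ecc1(L), ecc2(L), dcc1(L - 1), dcc2(L - 1);
  std::vector<PoolCache> pcc(L - 1);
  std::vector<arma::cube> skips(L - 1);
  std::vector<int> skip_c(L - 1);

  arma::cube h = x;
  int mi = 0;
  for (int l = 0; l < L; ++l) {
    h = conv_relu(h, enc[l].W1, enc[l].b1, ecc1[l]);
    h = conv_relu(h, enc[l].W2, enc[l].b2, ecc2[l]);
    if (l < L - 1) {
      skips[l] = h;
      skip_c[l] = h.n_slices;
      h = pool2(h, pcc[l]);
      if (use_masks) h %= mask[mi];
      mi++;
    }
  }
  for (int l = L - 2; l >= 0; --l) {
    arma::cube u = up2(h);
    if (use_masks) u %= mask[mi];
    mi++;
    arma::cube cat = arma::join_slices(u, skips[l]);
    h = conv_relu(cat, dec[l].W1, dec[l].b1, dcc1[l]);
    h = conv_relu(h, dec[l].W2, dec[l].b2, dcc2[l]);
  }
  // linear 1x1 head (single output channel)
  arma::mat hm = cube_to_mat(h);             // HW x C1
  arma::vec yv = hm * outW.t() + outb(0);
  arma::mat y(yv.memptr(), h.n_rows, h.n_cols);

  if (target.n_elem == 0)
    return List::create(_["y"] = y);

  arma::mat resid = y - target;
  const double loss = arma::accu(resid % resid) / resid.n_elem;
  List out = List::create(_["y"] = y, _["loss"] = loss);
  if (!want_grad) return out;

  arma::mat dym = resid * (2.0 / resid.n_elem);  // dL/dy, H x W
  arma::vec dyv(dym.memptr(), dym.n_elem);
  arma::mat d_outW = dyv.t() * hm;              // 1 x C1
  arma::vec d_outb(1); d_outb(0) = arma::accu(dyv);
  arma::mat dhm = dyv * outW;                   // HW x C1
  arma::cube dh = mat_to_cube(dhm, h.n_rows, h.n_cols);

  List g_dec(L - 1), g_enc(L);
  std::vector<arma::cube> dskips(L - 1);
  mi = use_masks ? (int)mask.size() - 1 : 2 * (L - 1) - 1;
  for (int l = 0; l <= L - 2; ++l) {
    arma::mat dW2, dW1; arma::vec db2, db1;
    dh = conv_relu_bwd(dcc2[l], dec[l].W2, dh, dW2, db2);
    dh = conv_relu_bwd(dcc1[l], dec[l].W1, dh, dW1, db1);
    g_dec[l] = List::create(
      _["c1"] = List::create(_["W"] = dW1, _["b"] = db1),
      _["c2"] = List::create(_["W"] = dW2, _["b"] = db2));
    const int f_up = dh.n_slices - skip_c[l];
    arma::cube dup = dh.slices(0, f_up - 1);
    dskips[l] = dh.slices(f_up, dh.n_slices - 1);
    if (use_masks) dup %= mask[mi];
    mi--;
    dh = up2_bwd(dup);
  }
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) {
      if (use_masks) dh %= mask[mi];
      mi--;
      dh = pool2_bwd(pcc[l], dh);
      dh += dskips[l];
    }
    arma::mat dW2, dW1; arma::vec db2, db1;
    dh = conv_relu_bwd(ecc2[l], enc[l].W2, dh, dW2, db2);
    dh = conv_relu_bwd(ecc1[l], enc[l].W1, dh, dW1, db1);
    g_enc[l] = List::create(
      _["c1"] = List::create(_["W"] = dW1, _["b"] = db1),
      _["c2"] = List::create(_["W"] = dW2, _["b"] = db2));
  }
  out["grads"] = List::create(
    _["enc"] = g_enc, _["dec"] = g_dec,
    _["out"] = List::create(_["W"] = d_outW, _["b"] = d_outb));
  return out;
}
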