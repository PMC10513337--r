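// Low-level numerical kernels for the segmentation / VAE engines and for
// connected-component labeling. All state lives in R; these are pure functions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for odd square kernels with "same" zero padding.
// Column ordering: c * k*k + dy * k + dx  (must match the R-side weight layout).
static arma::mat im2col_same(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat col(H * W, k * k * C);
  arma::mat padded(H + 2 * pad, W + 2 * pad, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    padded.zeros();
    padded.submat(pad, pad, pad + H - 1, pad + W - 1) = x.slice(c);
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        col.col(c * k * k + dy * k + dx) =
          arma::vectorise(padded.submat(dy, dx, dy + H - 1, dx + W - 1));
      }
    }
  }
  return col;
}

// scatter-add transpose of im2col_same
static arma::cube col2im_same(const arma::mat& col, int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  arma::cube gx(H, W, C, arma::fill::zeros);
  arma::mat padded(H + 2 * pad, W + 2 * pad);
  for (int c = 0; c < C; ++c) {
    padded.zeros();
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        padded.submat(dy, dx, dy + H - 1, dx + W - 1) +=
          arma::reshape(col.col(c * k * k + dy * k + dx), H, W);
      }
    }
    gx.slice(c) = padded.submat(pad, pad, pad + H - 1, pad + W - 1);
  }
  return gx;
}

// [[Rcpp::export(name = ".cm_conv2d_fwd")]]
arma::cube cm_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat col = im2col_same(x, k);
  arma::mat y = col * w;            // (H*W) x Cout
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), H, W);
  return out;
}

// forward that also returns the im2col matrix so the backward pass can
// reuse it (the im2col rebuild otherwise dominates training time)
// [[Rcpp::export(name = ".cm_conv2d_fwd_col")]]
List cm_conv2d_fwd_col(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat col = im2col_same(x, k);
  arma::mat y = col * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), H, W);
  return List::create(_["y"] = out, _["col"] = col);
}

// backward using a cached im2col matrix
// [[Rcpp::export(name = ".cm_conv2d_bwd_col")]]
List cm_conv2d_bwd_col(const arma::mat& col, const arma::mat& w,
                       const arma::cube& gout, int H, int W, int Cin, int k) {
  const int Cout = w.n_cols;
  arma::mat gy(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    gy.col(c) = arma::vectorise(gout.slice(c));
  arma::mat gw = col.t() * gy;
  arma::vec gb = arma::sum(gy, 0).t();
  arma::mat gcol = gy * w.t();
  arma::cube gx = col2im_same(gcol, H, W, Cin, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cm_conv2d_bwd")]]
List cm_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& gout, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  arma::mat gy(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    gy.col(c) = arma::vectorise(gout.slice(c));
  arma::mat col = im2col_same(x, k);
  arma::mat gw = col.t() * gy;
  arma::vec gb = arma::sum(gy, 0).t();
  arma::mat gcol = gy * w.t();
  arma::cube gx = col2im_same(gcol, H, W, Cin, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled cube and 1-based argmax linear
// indices into each input slice (for the backward pass).
// [[Rcpp::export(name = ".cm_maxpool_fwd")]]
List cm_maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = s(bi, bj); int br = bi, bc = bj;
        if (s(bi + 1, bj) > best) { best = s(bi + 1, bj); br = bi + 1; bc = bj; }
        if (s(bi, bj + 1) > best) { best = s(bi, bj + 1); br = bi; bc = bj + 1; }
        if (s(bi + 1, bj + 1) > best) { best = s(bi + 1, bj + 1); br = bi + 1; bc = bj + 1; }
        y(i, j, c) = best;
        idx(i, j, c) = (arma::uword)(bc * H + br + 1);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cm_maxpool_bwd")]]
arma::cube cm_maxpool_bwd(const arma::ucube& idx, const arma::cube& gout,
                          int H, int W) {
  const int C = gout.n_slices, Ho = gout.n_rows, Wo = gout.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gx.slice(c)(idx(i, j, c) - 1) += gout(i, j, c);
  }
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export(name = ".cm_upsample_fwd")]]
arma::cube cm_upsample_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".cm_upsample_bwd")]]
arma::cube cm_upsample_bwd(const arma::cube& gout) {
  const int H = gout.n_rows / 2, W = gout.n_cols / 2, C = gout.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gout(2 * i, 2 * j, c) + gout(2 * i + 1, 2 * j, c) +
                      gout(2 * i, 2 * j + 1, c) + gout(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// Connected-component labeling by breadth-first search. Components are
// numbered 1..K in raster-scan (column-major, as R stores matrices is
// column-major; we scan row-major over (row, col) to match the documented
// "raster-scan order of first pixel" convention).
// [[Rcpp::export(name = ".cm_label_components")]]
IntegerMatrix cm_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qr(H * W), qc(H * W);
  const int n8r[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int n8c[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int n4r[4] = {-1, 1, 0, 0};
  const int n4c[4] = {0, 0, -1, 1};  // order irrelevant for labeling
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? n8r : n4r;
  const int* dc = (connectivity == 8) ? n8c : n4c;
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qr[tail] = i; qc[tail] = j; ++tail;
      lab(i, j) = next;
      while (head < tail) {
        int r = qr[head], c = qc[head]; ++head;
        for (int t = 0; t < nn; ++t) {
          int r2 = r + dr[t], c2 = c + dc[t];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            qr[tail] = r2; qc[tail] = c2; ++tail;
          }
        }
      }
    }
  }
  return lab;
}
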