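// Low-level tensor kernels for the segmentation network.
//
// Layout conventions, shared with the R side:
//   * feature tensors are arma::cube (H, W, C) == R array dim c(H, W, C)
//   * conv weights are (Cout, Cin*kh*kw); the row index inside one im2col
//     column is c*kh*kw + ki + kh*kj (channel-major, then kernel row/col)
//   * transposed-conv weights are (Cin, Cout*kh*kw) with the same inner order
// All kernels are single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline int conv_out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(C * kh * kw, Ho * Wo, fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride + ki - pad;
            if (hi < 0 || hi >= H) continue;
            out(c * kh * kw + ki + kh * kj, col) = x(hi, wi, c);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add of im2col columns back onto an (H, W, C) cube
static void col2im_acc(cube& out, const mat& cols, int kh, int kw,
                       int stride, int pad, int Ho, int Wo) {
  const int H = out.n_rows, W = out.n_cols, C = out.n_slices;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride + ki - pad;
            if (hi < 0 || hi >= H) continue;
            out(hi, wi, c) += cols(c * kh * kw + ki + kh * kj, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fw_cpp(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, int kh, int kw,
                         int stride, int pad) {
  const int Ho = conv_out_dim(x.n_rows, kh, stride, pad);
  const int Wo = conv_out_dim(x.n_cols, kw, stride, pad);
  mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat y = W * cols;  // (Cout, Ho*Wo)
  y.each_col() += b;
  cube out(Ho, Wo, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    out.slice(c) = reshape(y.row(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(const arma::cube& x, const arma::mat& W,
                   const arma::cube& gout, int kh, int kw,
                   int stride, int pad) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  mat gy(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    gy.row(c) = vectorise(gout.slice(c)).t();
  mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat gW = gy * cols.t();
  vec gb = sum(gy, 1);
  mat gcols = W.t() * gy;
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_acc(gx, gcols, kh, kw, stride, pad, Ho, Wo);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// transposed convolution: out spatial = (in - 1) * stride + k - 2 * pad
// [[Rcpp::export]]
arma::cube convt2d_fw_cpp(const arma::cube& x, const arma::mat& Wt,
                          const arma::vec& b, int kh, int kw,
                          int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = Wt.n_cols / (kh * kw);
  const int Ho = (H - 1) * stride + kh - 2 * pad;
  const int Wo = (W - 1) * stride + kw - 2 * pad;
  mat xm(Cin, H * W);
  for (int c = 0; c < Cin; ++c)
    xm.row(c) = vectorise(x.slice(c)).t();
  mat cols = Wt.t() * xm;  // (Cout*kh*kw, H*W)
  cube out(Ho, Wo, Cout, fill::zeros);
  col2im_acc(out, cols, kh, kw, stride, pad, H, W);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) += b(c);
  return out;
}

// [[Rcpp::export]]
List convt2d_bw_cpp(const arma::cube& x, const arma::mat& Wt,
                    const arma::cube& gout, int kh, int kw,
                    int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  mat gcols = im2col(gout, kh, kw, stride, pad, H, W);
  mat xm(Cin, H * W);
  for (int c = 0; c < Cin; ++c)
    xm.row(c) = vectorise(x.slice(c)).t();
  mat gW = xm * gcols.t();   // (Cin, Cout*kh*kw)
  mat gxm = Wt * gcols;      // (Cin, H*W)
  cube gx(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    gx.slice(c) = reshape(gxm.row(c), H, W);
  vec gb(Cout);
  for (int c = 0; c < Cout; ++c)
    gb(c) = accu(gout.slice(c));
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// adaptive average pooling to an (oh, ow) grid; bin edges follow the
// floor/ceil convention so bins tile the input exactly
// [[Rcpp::export]]
arma::cube adapt_avgpool_fw_cpp(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(oh, ow, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < ow; ++j) {
      const int w0 = (j * W) / ow, w1 = ((j + 1) * W + ow - 1) / ow;
      for (int i = 0; i < oh; ++i) {
        const int h0 = (i * H) / oh, h1 = ((i + 1) * H + oh - 1) / oh;
        out(i, j, c) = accu(x.slice(c).submat(h0, w0, h1 - 1, w1 - 1)) /
          double((h1 - h0) * (w1 - w0));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube adapt_avgpool_bw_cpp(const arma::cube& gout, int H, int W) {
  const int oh = gout.n_rows, ow = gout.n_cols, C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < ow; ++j) {
      const int w0 = (j * W) / ow, w1 = ((j + 1) * W + ow - 1) / ow;
      for (int i = 0; i < oh; ++i) {
        const int h0 = (i * H) / oh, h1 = ((i + 1) * H + oh - 1) / oh;
        const double g = gout(i, j, c) / double((h1 - h0) * (w1 - w0));
        gx.slice(c).submat(h0, w0, h1 - 1, w1 - 1) += g;
      }
    }
  }
  return gx;
}

// bilinear resize, half-pixel centres (align_corners = false)
// [[Rcpp::export]]
arma::cube bilinear_fw_cpp(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(oh, ow, C);
  const double sh = double(H) / oh, sw = double(W) / ow;
  for (int j = 0; j < ow; ++j) {
    double fj = (j + 0.5) * sw - 0.5;
    if (fj < 0) fj = 0; if (fj > W - 1) fj = W - 1;
    const int j0 = int(std::floor(fj)), j1 = std::min(j0 + 1, W - 1);
    const double dj = fj - j0;
    for (int i = 0; i < oh; ++i) {
      double fi = (i + 0.5) * sh - 0.5;
      if (fi < 0) fi = 0; if (fi > H - 1) fi = H - 1;
      const int i0 = int(std::floor(fi)), i1 = std::min(i0 + 1, H - 1);
      const double di = fi - i0;
      for (int c = 0; c < C; ++c)
        out(i, j, c) =
          (1 - di) * (1 - dj) * x(i0, j0, c) + (1 - di) * dj * x(i0, j1, c) +
          di * (1 - dj) * x(i1, j0, c) + di * dj * x(i1, j1, c);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube bilinear_bw_cpp(const arma::cube& gout, int H, int W) {
  const int oh = gout.n_rows, ow = gout.n_cols, C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  const double sh = double(H) / oh, sw = double(W) / ow;
  for (int j = 0; j < ow; ++j) {
    double fj = (j + 0.5) * sw - 0.5;
    if (fj < 0) fj = 0; if (fj > W - 1) fj = W - 1;
    const int j0 = int(std::floor(fj)), j1 = std::min(j0 + 1, W - 1);
    const double dj = fj - j0;
    for (int i = 0; i < oh; ++i) {
      double fi = (i + 0.5) * sh - 0.5;
      if (fi < 0) fi = 0; if (fi > H - 1) fi = H - 1;
      const int i0 = int(std::floor(fi)), i1 = std::min(i0 + 1, H - 1);
      const double di = fi - i0;
      for (int c = 0; c < C; ++c) {
        const double g = gout(i, j, c);
        gx(i0, j0, c) += (1 - di) * (1 - dj) * g;
        gx(i0, j1, c) += (1 - di) * dj * g;
        gx(i1, j0, c) += di * (1 - dj) * g;
        gx(i1, j1, c) += di * dj * g;
      }
    }
  }
  return gx;
}
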