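// Low-level CPU kernels for the convolutional networks and image resampling.
// Feature maps are arma::cube with layout (height, width, channels), which
// matches an R array of dim c(h, w, c). Convolution is im2col + GEMM; the
// column ordering (row offset fastest, then column offset, then channel) is a
// private contract between the forward and backward kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int ho, int wo) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int K = kh * kw * c;
  mat cols(K, (uword)(ho * wo), fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = ch * kh * kw + dj * kh + di;
        for (int oc = 0; oc < wo; ++oc) {
          const int ic = oc * stride - pad + dj;
          if (ic < 0 || ic >= w) continue;
          for (int orow = 0; orow < ho; ++orow) {
            const int ir = orow * stride - pad + di;
            if (ir < 0 || ir >= h) continue;
            cols(r, (uword)(oc * ho + orow)) = x(ir, ic, ch);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, int h, int w, int c, int kh, int kw,
                   int stride, int pad, int ho, int wo) {
  cube x(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = ch * kh * kw + dj * kh + di;
        for (int oc = 0; oc < wo; ++oc) {
          const int ic = oc * stride - pad + dj;
          if (ic < 0 || ic >= w) continue;
          for (int orow = 0; orow < ho; ++orow) {
            const int ir = orow * stride - pad + di;
            if (ir < 0 || ir >= h) continue;
            x(ir, ic, ch) += cols(r, (uword)(oc * ho + orow));
          }
        }
      }
    }
  }
  return x;
}

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Forward 2-D convolution. W is (kh*kw*c_in) x c_out, b length c_out.
// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad) {
  const int ho = out_dim(x.n_rows, kh, stride, pad);
  const int wo = out_dim(x.n_cols, kw, stride, pad);
  const int cout = W.n_cols;
  mat cols = im2col(x, kh, kw, stride, pad, ho, wo);
  mat out_mat = cols.t() * W;           // (ho*wo) x c_out
  out_mat.each_row() += b.t();
  cube out(ho, wo, cout);
  std::memcpy(out.memptr(), out_mat.memptr(),
              sizeof(double) * out_mat.n_elem);
  return out;
}

// Backward pass: gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gout, int kh, int kw, int stride,
                          int pad) {
  const int ho = gout.n_rows, wo = gout.n_cols, cout = gout.n_slices;
  mat gout_mat((uword)(ho * wo), cout);
  std::memcpy(gout_mat.memptr(), gout.memptr(),
              sizeof(double) * gout_mat.n_elem);
  mat cols = im2col(x, kh, kw, stride, pad, ho, wo);
  mat gW = cols * gout_mat;             // K x c_out
  vec gb = sum(gout_mat, 0).t();
  mat gcols = W * gout_mat.t();         // K x (ho*wo)
  cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride,
                   pad, ho, wo);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Nearest-neighbour x2 upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  cube out(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword ch = 0; ch < x.n_slices; ++ch)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, ch);
        out(2 * i, 2 * j, ch) = v;
        out(2 * i + 1, 2 * j, ch) = v;
        out(2 * i, 2 * j + 1, ch) = v;
        out(2 * i + 1, 2 * j + 1, ch) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& g) {
  cube out(g.n_rows / 2, g.n_cols / 2, g.n_slices);
  for (uword ch = 0; ch < g.n_slices; ++ch)
    for (uword j = 0; j < out.n_cols; ++j)
      for (uword i = 0; i < out.n_rows; ++i)
        out(i, j, ch) = g(2 * i, 2 * j, ch) + g(2 * i + 1, 2 * j, ch) +
                        g(2 * i, 2 * j + 1, ch) + g(2 * i + 1, 2 * j + 1, ch);
  return out;
}

// Bilinear resize of a single-channel image with edge-aligned sampling.
// [[Rcpp::export]]
arma::mat cpp_resize_bilinear(const arma::mat& img, int out_h, int out_w) {
  const int h = img.n_rows, w = img.n_cols;
  mat out(out_h, out_w);
  const double sr = (double)h / out_h, sc = (double)w / out_w;
  for (int j = 0; j < out_w; ++j) {
    double fc = (j + 0.5) * sc - 0.5;
    if (fc < 0) fc = 0;
    if (fc > w - 1) fc = w - 1;
    const int c0 = (int)std::floor(fc), c1 = std::min(c0 + 1, w - 1);
    const double wc = fc - c0;
    for (int i = 0; i < out_h; ++i) {
      double fr = (i + 0.5) * sr - 0.5;
      if (fr < 0) fr = 0;
      if (fr > h - 1) fr = h - 1;
      const int r0 = (int)std::floor(fr), r1 = std::min(r0 + 1, h - 1);
      const double wr = fr - r0;
      out(i, j) = (1 - wr) * ((1 - wc) * img(r0, c0) + wc * img(r0, c1)) +
                  wr * ((1 - wc) * img(r1, c0) + wc * img(r1, c1));
    }
  }
  return out;
}
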