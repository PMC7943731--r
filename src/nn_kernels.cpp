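// Low-level forward/backward kernels for the convolutional reconstruction
// networks.  All activations are H x W x C arrays (R column-major layout,
// which matches arma::cube).  Convolution weights are stored as
// (k*k*Cin) x Cout matrices whose row index is dy + k*dx + k*k*ci
// (0-based), i.e. the column-major flattening of a (k, k, Cin) array.
// Stride is always 1 with "same" zero padding; kernels are odd-sized.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_same(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = k / 2;
  arma::mat cols(H * W, k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const double* slice = x.slice_memptr(ci);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        double* dst0 = cols.colptr(dy + k * dx + k * k * ci);
        const int oy = dy - pad;                 // source row offset
        const int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        if (y1 <= y0) continue;
        for (int xx = 0; xx < W; ++xx) {
          const int sx = xx + dx - pad;
          if (sx < 0 || sx >= W) continue;
          const double* src = slice + (size_t)H * sx + oy;
          double* dst = dst0 + (size_t)H * xx;
          std::memcpy(dst + y0, src + y0, (y1 - y0) * sizeof(double));
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im_same(const arma::mat& cols, int H, int W, int C,
                              int k) {
  const int pad = k / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    double* slice = out.slice_memptr(ci);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const double* src0 = cols.colptr(dy + k * dx + k * k * ci);
        const int oy = dy - pad;
        const int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        if (y1 <= y0) continue;
        for (int xx = 0; xx < W; ++xx) {
          const int sx = xx + dx - pad;
          if (sx < 0 || sx >= W) continue;
          double* dst = slice + (size_t)H * sx + oy;
          const double* src = src0 + (size_t)H * xx;
          for (int yy = y0; yy < y1; ++yy) dst[yy] += src[yy];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2dFw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  arma::mat cols = im2col_same(x, k);
  arma::mat om = cols * W;         // (H*W) x Cout
  om.each_row() += b.t();
  arma::cube out(om.memptr(), H, Wd, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv2dBw")]]
List conv2d_bw(const arma::cube& x, const arma::mat& W, const arma::cube& go,
               int k) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = go.n_slices;
  arma::mat gom(const_cast<double*>(go.memptr()), H * Wd, Cout, false, true);
  arma::mat cols = im2col_same(x, k);
  arma::mat gW = cols.t() * gom;
  arma::vec gb = arma::sum(gom, 0).t();
  arma::mat gcols = gom * W.t();
  arma::cube gx = col2im_same(gcols, H, Wd, C, k);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2.  Returns the pooled cube and the 0-based
// linear indices (into the input cube) of each maximum, for the backward
// pass.  Ties take the first element in column-major scan order.
// [[Rcpp::export(name = ".maxpool2Fw")]]
List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int dx = 0; dx < 2; ++dx) {
          for (int dy = 0; dy < 2; ++dy) {
            const int yy = 2 * yo + dy, xx = 2 * xo + dx;
            const double v = x(yy, xx, c);
            if (v > best) {
              best = v;
              bi = yy + H * xx + H * W * c;
            }
          }
        }
        out(yo, xo, c) = best;
        idx[p++] = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2Bw")]]
arma::cube maxpool2_bw(const IntegerVector& idx, const arma::cube& go, int H,
                       int W, int C) {
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = go.memptr();
  for (int p = 0; p < (int)idx.size(); ++p) gx(idx[p]) += g[p];
  return gx;
}

// Transposed convolution, 2x2 kernel, stride 2 (doubles H and W).
// Weights: (4*Cin) x Cout with row index dy + 2*dx + 4*ci.
// [[Rcpp::export(name = ".upconv2Fw")]]
arma::cube upconv2_fw(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  arma::cube out(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) out.slice(co).fill(b(co));
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dx = 0; dx < 2; ++dx) {
        for (int dy = 0; dy < 2; ++dy) {
          const double w = W(dy + 2 * dx + 4 * ci, co);
          if (w == 0.0) continue;
          for (int xx = 0; xx < Wd; ++xx) {
            for (int yy = 0; yy < H; ++yy) {
              out(2 * yy + dy, 2 * xx + dx, co) += w * x(yy, xx, ci);
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".upconv2Bw")]]
List upconv2_bw(const arma::cube& x, const arma::mat& W,
                const arma::cube& go) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = go.n_slices;
  arma::cube gx(H, Wd, Cin, arma::fill::zeros);
  arma::mat gW(4 * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    gb(co) = arma::accu(go.slice(co));
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dx = 0; dx < 2; ++dx) {
        for (int dy = 0; dy < 2; ++dy) {
          const double w = W(dy + 2 * dx + 4 * ci, co);
          double acc = 0.0;
          for (int xx = 0; xx < Wd; ++xx) {
            for (int yy = 0; yy < H; ++yy) {
              const double g = go(2 * yy + dy, 2 * xx + dx, co);
              gx(yy, xx, ci) += w * g;
              acc += x(yy, xx, ci) * g;
            }
          }
          gW(dy + 2 * dx + 4 * ci, co) = acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
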