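// Convolution / pooling kernels for the GAF network stack.
// Layout: images are H x W x C arma::cubes; a conv weight arriving from R is a
// (Cout x kh*kw*Cin) matrix whose rows unroll the kernel in (kh, kw, Cin)
// column-major order, matching as.vector() on an array(dim = c(kh, kw, Cin)).
// All convolutions are stride-1 with "same" zero padding (odd kernels).
//
// The unrolled ("im2col") matrix is kept transposed, (H*W) x (kh*kw*Cin), so
// every fill is a contiguous run of input column segments; the backward pass
// re-unrolls the cached layer input instead of shipping the large matrix
// across the R boundary.

#ifndef ARMA_NO_DEBUG
#define ARMA_NO_DEBUG
#endif
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// (H*W) x (kh*kw*C) unrolled input with zero padding
static arma::mat im2colT(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat cols(H * W, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.slice_memptr(c);
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        double* dst = cols.colptr(p + q * kh + c * kh * kw);
        const int i_lo = std::max(0, ph - p);
        const int i_hi = std::min(H, H + ph - p);
        if (i_hi <= i_lo) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j + q - pw;
          if (jj < 0 || jj >= W) continue;
          std::memcpy(dst + j * H + i_lo, src + jj * H + i_lo + p - ph,
                      (i_hi - i_lo) * sizeof(double));
        }
      }
    }
  }
  return cols;
}

static arma::cube col2imT(const arma::mat& cols, int H, int W, int C,
                          int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = x.slice_memptr(c);
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const double* src = cols.colptr(p + q * kh + c * kh * kw);
        const int i_lo = std::max(0, ph - p);
        const int i_hi = std::min(H, H + ph - p);
        if (i_hi <= i_lo) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j + q - pw;
          if (jj < 0 || jj >= W) continue;
          double* d = dst + jj * H + i_lo + p - ph;
          const double* s = src + j * H + i_lo;
          for (int i = 0; i < i_hi - i_lo; ++i) d[i] += s[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& Wm,
                      const arma::vec& b, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_rows;
  arma::mat cols = im2colT(x, kh, kw);
  arma::mat outm = cols * Wm.t();      // (H*W) x Cout
  outm.each_row() += b.t();
  arma::cube out(H, W, Cout);
  std::memcpy(out.memptr(), outm.memptr(), outm.n_elem * sizeof(double));
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::cube& gout,
                const arma::mat& Wm, int kh, int kw) {
  const int H = gout.n_rows, W = gout.n_cols, Cout = gout.n_slices;
  const int Cin = x.n_slices;
  arma::mat cols = im2colT(x, kh, kw);
  // a cube's memory is already the (H*W) x Cout matrix, column-major
  const arma::mat gm(const_cast<double*>(gout.memptr()), H * W, Cout, false);
  arma::mat dW = gm.t() * cols;        // Cout x (kh*kw*Cin)
  arma::vec db = arma::sum(gm, 0).t();
  arma::mat dcols = gm * Wm;           // (H*W) x (kh*kw*Cin)
  arma::cube dx = col2imT(dcols, H, W, Cin, kh, kw);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Max pooling, window (ph x pw) with the same strides; trailing rows/cols
// that do not fill a window are dropped (floor semantics).
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const arma::cube& x, int ph, int pw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / ph, Wo = W / pw;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);          // linear index within the input slice
  for (int c = 0; c < C; ++c) {
    const double* sl = x.slice_memptr(c);
    double* o = out.slice_memptr(c);
    arma::uword* ix = idx.slice_memptr(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        arma::uword bidx = 0;
        for (int q = 0; q < pw; ++q) {
          const int jj = j * pw + q;
          for (int p = 0; p < ph; ++p) {
            const int ii = i * ph + p;
            const double v = sl[ii + jj * H];
            if (v > best) { best = v; bidx = ii + jj * H; }
          }
        }
        o[i + j * Ho] = best;
        ix[i + j * Ho] = bidx;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube& gout, const arma::ucube& idx,
                       int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* sl = dx.slice_memptr(c);
    const double* g = gout.slice_memptr(c);
    const arma::uword* ix = idx.slice_memptr(c);
    for (int k = 0; k < Ho * Wo; ++k) sl[ix[k]] += g[k];
  }
  return dx;
}
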