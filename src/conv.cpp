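// Minimal 2-D convolution kernels (same padding, arbitrary stride) used by
// the convolutional variational autoencoder. Layout: images are H x W x C
// cubes, filter banks are (C_out) x (kh*kw*C_in) matrices, so a forward pass
// over a whole minibatch is a single GEMM against the concatenated im2col
// patch matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void pad_amounts(int in, int k, int s, int &out, int &pad_lo) {
  out = (in + s - 1) / s;                      // ceil(in / s), "same" padding
  int pad = std::max((out - 1) * s + k - in, 0);
  pad_lo = pad / 2;
}

static void im2col(const cube &x, int kh, int kw, int sh, int sw,
                   int Hout, int Wout, int pt, int pl, double *colbase) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int patch = kh * kw * C;
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      double *cptr = colbase + static_cast<size_t>(ow * Hout + oh) * patch;
      for (int c = 0; c < C; ++c) {
        const double *xc = x.slice(c).memptr();
        for (int j = 0; j < kw; ++j) {
          const int iw = ow * sw - pl + j;
          if (iw < 0 || iw >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int ih = oh * sh - pt + i;
            if (ih < 0 || ih >= H) continue;
            cptr[c * kh * kw + j * kh + i] = xc[iw * H + ih];
          }
        }
      }
    }
  }
}

static void col2im(const double *colbase, int H, int W, int C, int kh, int kw,
                   int sh, int sw, int Hout, int Wout, int pt, int pl,
                   cube &dx) {
  const int patch = kh * kw * C;
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const double *cptr = colbase + static_cast<size_t>(ow * Hout + oh) * patch;
      for (int c = 0; c < C; ++c) {
        double *xc = dx.slice(c).memptr();
        for (int j = 0; j < kw; ++j) {
          const int iw = ow * sw - pl + j;
          if (iw < 0 || iw >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int ih = oh * sh - pt + i;
            if (ih < 0 || ih >= H) continue;
            xc[iw * H + ih] += cptr[c * kh * kw + j * kh + i];
          }
        }
      }
    }
  }
}

// Forward convolution over a batch; one GEMM for all images. `relu` applies
// the activation in place.
// [[Rcpp::export]]
Rcpp::List conv2d_forward_batch(const Rcpp::List &xs, const arma::mat &w,
                                const arma::vec &b, int kh, int kw, int sh,
                                int sw, bool relu) {
  const int B = xs.size();
  cube x0 = Rcpp::as<cube>(xs[0]);
  int Hout, Wout, pt, pl;
  pad_amounts(x0.n_rows, kh, sh, Hout, pt);
  pad_amounts(x0.n_cols, kw, sw, Wout, pl);
  const int patch = kh * kw * x0.n_slices;
  const int per = Hout * Wout;
  mat cols(patch, static_cast<size_t>(B) * per, fill::zeros);
  for (int i = 0; i < B; ++i) {
    cube xi = Rcpp::as<cube>(xs[i]);
    im2col(xi, kh, kw, sh, sw, Hout, Wout, pt, pl,
           cols.colptr(static_cast<size_t>(i) * per));
  }
  mat y = w * cols;                            // C_out x (B*per)
  y.each_col() += b;
  if (relu) y.for_each([](double &v) { if (v < 0) v = 0; });
  const int Cout = w.n_rows;
  Rcpp::List out(B);
  for (int i = 0; i < B; ++i) {
    cube oi(Hout, Wout, Cout);
    for (int c = 0; c < Cout; ++c)
      oi.slice(c) = reshape(y.submat(c, static_cast<size_t>(i) * per, c,
                                     static_cast<size_t>(i + 1) * per - 1),
                            Hout, Wout);
    out[i] = oi;
  }
  return out;
}

// Backward pass for the batch. `dys` are gradients w.r.t. the
// pre-activation outputs. Returns per-image input gradients and the weight
// and bias gradients summed over the batch.
// [[Rcpp::export]]
Rcpp::List conv2d_backward_batch(const Rcpp::List &xs, const arma::mat &w,
                                 const Rcpp::List &dys, int kh, int kw,
                                 int sh, int sw) {
  const int B = xs.size();
  cube x0 = Rcpp::as<cube>(xs[0]);
  const int H = x0.n_rows, W = x0.n_cols, C = x0.n_slices;
  int Hout, Wout, pt, pl;
  pad_amounts(H, kh, sh, Hout, pt);
  pad_amounts(W, kw, sw, Wout, pl);
  const int patch = kh * kw * C;
  const int per = Hout * Wout;
  const int Cout = w.n_rows;
  mat cols(patch, static_cast<size_t>(B) * per, fill::zeros);
  mat dyf(Cout, static_cast<size_t>(B) * per);
  for (int i = 0; i < B; ++i) {
    cube xi = Rcpp::as<cube>(xs[i]);
    im2col(xi, kh, kw, sh, sw, Hout, Wout, pt, pl,
           cols.colptr(static_cast<size_t>(i) * per));
    cube dyi = Rcpp::as<cube>(dys[i]);
    for (int c = 0; c < Cout; ++c)
      dyf.submat(c, static_cast<size_t>(i) * per, c,
                 static_cast<size_t>(i + 1) * per - 1) =
        vectorise(dyi.slice(c)).t();
  }
  mat dw = dyf * cols.t();
  vec db = sum(dyf, 1);
  mat dcols = w.t() * dyf;
  Rcpp::List dxs(B);
  for (int i = 0; i < B; ++i) {
    cube dxi(H, W, C, fill::zeros);
    col2im(dcols.colptr(static_cast<size_t>(i) * per), H, W, C, kh, kw, sh,
           sw, Hout, Wout, pt, pl, dxi);
    dxs[i] = dxi;
  }
  return Rcpp::List::create(Rcpp::Named("dxs") = dxs,
                            Rcpp::Named("dw") = dw, Rcpp::Named("db") = db);
}

// Single-image wrappers kept for unit-level checks of the kernels.
// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube &x, const arma::mat &w,
                          const arma::vec &b, int kh, int kw, int sh,
                          int sw) {
  Rcpp::List xs = Rcpp::List::create(x);
  Rcpp::List out = conv2d_forward_batch(xs, w, b, kh, kw, sh, sw, false);
  return Rcpp::as<cube>(out[0]);
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube &x, const arma::mat &w,
                           const arma::cube &dy, int kh, int kw, int sh,
                           int sw) {
  Rcpp::List xs = Rcpp::List::create(x);
  Rcpp::List dys = Rcpp::List::create(dy);
  Rcpp::List res = conv2d_backward_batch(xs, w, dys, kh, kw, sh, sw);
  Rcpp::List dxs = res["dxs"];
  return Rcpp::List::create(Rcpp::Named("dx") = dxs[0],
                            Rcpp::Named("dw") = res["dw"],
                            Rcpp::Named("db") = res["db"]);
}
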