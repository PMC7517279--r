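// Low-level tensor kernels for the AlexNet-style quality network.
// Layout: activations are arma::cube (H x W x C); convolution weights are
// (Cout x k*k*Cin_per_group) matrices whose columns enumerate (kh, kw, c)
// with kh fastest; output pixels enumerate (oh, ow) with oh fastest, so a
// reshape of one GEMM row recovers the (Hout x Wout) map column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int k, int stride, int pad,
                  int c0, int nc, int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols;
  mat cols(k * k * nc, Hout * Wout, fill::zeros);
  for (int c = 0; c < nc; ++c) {
    const mat& plane = x.slice(c0 + c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = dh + k * dw + k * k * c;
        for (int ow = 0; ow < Wout; ++ow) {
          const int w = ow * stride + dw - pad;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Hout; ++oh) {
            const int h = oh * stride + dh - pad;
            if (h < 0 || h >= H) continue;
            cols(r, oh + Hout * ow) = plane(h, w);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(cube& dx, const mat& dcols, int k, int stride, int pad,
                       int c0, int nc, int Hout, int Wout) {
  const int H = dx.n_rows, W = dx.n_cols;
  for (int c = 0; c < nc; ++c) {
    mat& plane = dx.slice(c0 + c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = dh + k * dw + k * k * c;
        for (int ow = 0; ow < Wout; ++ow) {
          const int w = ow * stride + dw - pad;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Hout; ++oh) {
            const int h = oh * stride + dh - pad;
            if (h < 0 || h >= H) continue;
            plane(h, w) += dcols(r, oh + Hout * ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv_forward(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int k, int stride, int pad,
                        int groups) {
  const int Cin = x.n_slices;
  const int Cout = W.n_rows;
  const int cing = Cin / groups, coutg = Cout / groups;
  const int Hout = (x.n_rows + 2 * pad - k) / stride + 1;
  const int Wout = (x.n_cols + 2 * pad - k) / stride + 1;
  cube y(Hout, Wout, Cout);
  for (int g = 0; g < groups; ++g) {
    mat cols = im2col(x, k, stride, pad, g * cing, cing, Hout, Wout);
    mat out = W.rows(g * coutg, (g + 1) * coutg - 1) * cols;
    for (int co = 0; co < coutg; ++co) {
      y.slice(g * coutg + co) =
        reshape(out.row(co).t(), Hout, Wout) + b(g * coutg + co);
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv_backward(const arma::cube& x, const arma::mat& W,
                         const arma::cube& dy, int k, int stride, int pad,
                         int groups) {
  const int Cin = x.n_slices;
  const int Cout = W.n_rows;
  const int cing = Cin / groups, coutg = Cout / groups;
  const int Hout = dy.n_rows, Wout = dy.n_cols;
  cube dx(x.n_rows, x.n_cols, Cin, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(Cout, fill::zeros);
  for (int g = 0; g < groups; ++g) {
    mat dyg(coutg, Hout * Wout);
    for (int co = 0; co < coutg; ++co) {
      dyg.row(co) = vectorise(dy.slice(g * coutg + co)).t();
      db(g * coutg + co) = accu(dy.slice(g * coutg + co));
    }
    mat cols = im2col(x, k, stride, pad, g * cing, cing, Hout, Wout);
    dW.rows(g * coutg, (g + 1) * coutg - 1) = dyg * cols.t();
    mat dcols = W.rows(g * coutg, (g + 1) * coutg - 1).t() * dyg;
    col2im_add(dx, dcols, k, stride, pad, g * cing, cing, Hout, Wout);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Cross-channel local response normalisation:
//   y_i = x_i / (kk + alpha * sum_{j in window(i)} x_j^2)^beta
// with a window of n channels centred on i (AlexNet: n=5, alpha=1e-4,
// beta=0.75, kk=2).

// [[Rcpp::export]]
Rcpp::List lrn_forward(const arma::cube& x, int n, double alpha, double beta,
                       double kk) {
  const int C = x.n_slices;
  const int half = (n - 1) / 2;
  cube sq = square(x);
  cube denom(x.n_rows, x.n_cols, C);
  for (int i = 0; i < C; ++i) {
    mat s(x.n_rows, x.n_cols, fill::zeros);
    for (int j = std::max(0, i - half); j <= std::min(C - 1, i + half); ++j)
      s += sq.slice(j);
    denom.slice(i) = kk + alpha * s;
  }
  cube y = x % pow(denom, -beta);
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("denom") = denom);
}

// [[Rcpp::export]]
arma::cube lrn_backward(const arma::cube& x, const arma::cube& denom,
                        const arma::cube& dy, int n, double alpha,
                        double beta, double kk) {
  const int C = x.n_slices;
  const int half = (n - 1) / 2;
  cube t = dy % x % pow(denom, -beta - 1.0);  // dy_j x_j d_j^{-beta-1}
  cube dx(x.n_rows, x.n_cols, C);
  for (int i = 0; i < C; ++i) {
    mat s(x.n_rows, x.n_cols, fill::zeros);
    for (int j = std::max(0, i - half); j <= std::min(C - 1, i + half); ++j)
      s += t.slice(j);
    dx.slice(i) = dy.slice(i) % pow(denom.slice(i), -beta) -
      2.0 * alpha * beta * x.slice(i) % s;
  }
  return dx;
}

// [[Rcpp::export]]
Rcpp::List maxpool_forward(const arma::cube& x, int k, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = (H - k) / stride + 1;
  const int Wout = (W - k) / stride + 1;
  cube y(Hout, Wout, C);
  ucube amax(Hout, Wout, C);  // flat (h + H*w) index of the winner
  for (int c = 0; c < C; ++c) {
    const mat& plane = x.slice(c);
    for (int ow = 0; ow < Wout; ++ow) {
      for (int oh = 0; oh < Hout; ++oh) {
        double best = -datum::inf;
        uword bidx = 0;
        for (int dw = 0; dw < k; ++dw) {
          for (int dh = 0; dh < k; ++dh) {
            const int h = oh * stride + dh, w = ow * stride + dw;
            const double v = plane(h, w);
            if (v > best) { best = v; bidx = h + H * w; }
          }
        }
        y(oh, ow, c) = best;
        amax(oh, ow, c) = bidx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::cube maxpool_backward(const arma::ucube& argmax, const arma::cube& dy,
                            int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& plane = dx.slice(c);
    for (uword j = 0; j < dy.n_cols; ++j)
      for (uword i = 0; i < dy.n_rows; ++i)
        plane(argmax(i, j, c)) += dy(i, j, c);
  }
  return dx;
}
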