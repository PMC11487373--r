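// Minimal convolution / pooling kernels for the embedding network.
// Tensors follow the package convention: activations are (H, W, C, N)
// column-major R arrays, convolution weights are (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  int o = (in + 2 * pad - eff) / stride + 1;
  if (o < 1) stop("convolution/pooling output would be empty");
  return o;
}

// Unfold one sample x (H,W,C) into M of shape (Ho*Wo, kh*kw*C).
// Column ordering matches the R flattening of a (kh,kw,Cin) weight block.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * c);
        double* col = M.colptr(q);
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * stride - pad + kj * dil;
          if (j < 0 || j >= W) {
            for (int oi = 0; oi < Ho; ++oi) col[oi + (size_t)Ho * oj] = 0.0;
            continue;
          }
          const double* xcj = xc + (size_t)H * j;
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * stride - pad + ki * dil;
            col[oi + (size_t)Ho * oj] = (i >= 0 && i < H) ? xcj[i] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-accumulate the unfolded gradient G (Ho*Wo, kh*kw*C) back into gx.
static void col2im_acc(const arma::mat& G, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int dil,
                       int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * c);
        const double* col = G.colptr(q);
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * stride - pad + kj * dil;
          if (j < 0 || j >= W) continue;
          double* gcj = gc + (size_t)H * j;
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * stride - pad + ki * dil;
            if (i >= 0 && i < H) gcj[i] += col[oi + (size_t)Ho * oj];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector bias,
                            int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4) stop("expected 4-d input and weight arrays");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  if (bias.size() != Cout) stop("bias length must equal output channels");
  int Ho = out_dim(H, kh, stride, pad, dil);
  int Wo = out_dim(W, kw, stride, pad, dil);
  int K = kh * kw * Cin;

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(K, Cout);
  std::copy(w.begin(), w.end(), Wm.begin());
  arma::mat M(Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pad, dil, Ho, Wo, M);
    arma::mat O = M * Wm;
    for (int co = 0; co < Cout; ++co) O.col(co) += bias[co];
    std::copy(O.begin(), O.end(), out.begin() + (size_t)Ho * Wo * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gout,
                   int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch");
  int Ho = out_dim(H, kh, stride, pad, dil);
  int Wo = out_dim(W, kw, stride, pad, dil);
  int K = kh * kw * Cin;
  IntegerVector gd = gout.attr("dim");
  if (gd[0] != Ho || gd[1] != Wo || gd[2] != Cout || gd[3] != N)
    stop("gradient shape does not match convolution output");

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  arma::mat Wm(K, Cout);
  std::copy(w.begin(), w.end(), Wm.begin());
  arma::mat GW(K, Cout, arma::fill::zeros);
  arma::vec GB(Cout, arma::fill::zeros);
  arma::mat M(Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pad, dil, Ho, Wo, M);
    arma::mat G(Ho * Wo, Cout);
    std::copy(gout.begin() + (size_t)Ho * Wo * Cout * n,
              gout.begin() + (size_t)Ho * Wo * Cout * (n + 1), G.begin());
    GW += M.t() * G;
    GB += arma::sum(G, 0).t();
    arma::mat GM = G * Wm.t();
    col2im_acc(GM, H, W, C, kh, kw, stride, pad, dil, Ho, Wo,
               gx.begin() + (size_t)H * W * C * n);
  }
  std::copy(GW.begin(), GW.end(), gw.begin());
  std::copy(GB.begin(), GB.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_dim(H, k, stride, pad, 1);
  int Wo = out_dim(W, k, stride, pad, 1);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax((size_t)Ho * Wo * C * N);  // 0-based linear index into x

  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = amax.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)H * W * (c + (size_t)C * n);
      size_t pbase = (size_t)H * W * (c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            int j = oj * stride - pad + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int i = oi * stride - pad + ki;
              if (i < 0 || i >= H) continue;
              double v = plane[i + (size_t)H * j];
              if (v > best) { best = v; besti = i + H * j; }
            }
          }
          size_t o = oi + (size_t)Ho * (oj + (size_t)Wo * (c + (size_t)C * n));
          op[o] = best;
          ap[o] = (int)(pbase + besti);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(IntegerVector argmax, NumericVector gout,
                             IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  double* g = gx.begin();
  for (R_xlen_t t = 0; t < gout.size(); ++t) g[argmax[t]] += gout[t];
  return gx;
}
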