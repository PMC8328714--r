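// Low-level numeric kernels for the 2-D encoder-decoder network.
// Tensors are R arrays in column-major order with dim (H, W, C, N).
// Convolution weights have dim (kh, kw, Cin, Cout); stride is always 1 and
// padding is "same" for odd kernels (pad = (k - 1) / 2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* xs, int H, int W, int C,
                   int kh, int kw, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + j * kh + c * kh * kw;
        for (int w = 0; w < W; ++w) {
          const int sw = w + j - pw;
          if (sw < 0 || sw >= W) continue;
          const double* xcol = xc + (size_t)sw * H;
          double* crow = col.memptr() + r;  // stride = col.n_rows
          const size_t nr = col.n_rows;
          for (int h = 0; h < H; ++h) {
            const int sh = h + i - ph;
            if (sh < 0 || sh >= H) continue;
            crow[(size_t)(h + w * H) * nr] = xcol[sh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv forward");
  const int K = kh * kw * Cin, HW = H * W;
  arma::mat wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(K, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, col);
    arma::mat ymat = wmat.t() * col;  // Cout x HW
    double* ys = y.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bb = b[co];
      double* yc = ys + (size_t)co * HW;
      for (int p = 0; p < HW; ++p) yc[p] = ymat(co, p) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kh * kw * Cin, HW = H * W;
  arma::mat wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((size_t)HW * C * N), dw((size_t)K * Cout), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dwacc(dw.begin(), K, Cout, false, true);
  arma::mat col(K, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, col);
    arma::mat dymat(Cout, HW);
    const double* dys = dy.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dys + (size_t)co * HW;
      double acc = 0.0;
      for (int p = 0; p < HW; ++p) { dymat(co, p) = dyc[p]; acc += dyc[p]; }
      db[co] += acc;
    }
    dwacc += col * dymat.t();
    arma::mat dcol = wmat * dymat;  // K x HW
    // col2im: scatter-add back into dx
    double* dxs = dx.begin() + (size_t)n * HW * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxs + (size_t)c * HW;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int r = i + j * kh + c * kh * kw;
          for (int wI = 0; wI < W; ++wI) {
            const int sw = wI + j - pw;
            if (sw < 0 || sw >= W) continue;
            for (int hI = 0; hI < H; ++hI) {
              const int sh = hI + i - ph;
              if (sh < 0 || sh >= H) continue;
              dxc[sh + (size_t)sw * H] += dcol(r, hI + wI * H);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2, ceil mode (trailing odd row/col forms its own
// window). Returns pooled values and the flat 1-based index of each argmax.
// [[Rcpp::export]]
List nn_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const double* xc = x.begin() + base;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj) {
            const int wI = 2 * wo + dj;
            if (wI >= W) continue;
            for (int di = 0; di < 2; ++di) {
              const int hI = 2 * ho + di;
              if (hI >= H) continue;
              const double v = xc[hI + (size_t)wI * H];
              if (v > best) { best = v; bidx = base + hI + (size_t)wI * H; }
            }
          }
          // column-major output order is (ho fastest); recompute o explicitly
          o = (((size_t)n * C + c) * Wo + wo) * Ho + ho;
          y[o] = best;
          idx[o] = (int)(bidx + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  const R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Nearest-neighbour 2x upsampling: output (2H, 2W, C, N).
// [[Rcpp::export]]
NumericVector nn_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* yc = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* xcol = xc + (size_t)(wo / 2) * H;
        double* ycol = yc + (size_t)wo * Ho;
        for (int ho = 0; ho < Ho; ++ho) ycol[ho] = xcol[ho / 2];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dyc = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* dxc = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* dycol = dyc + (size_t)wo * Ho;
        double* dxcol = dxc + (size_t)(wo / 2) * H;
        for (int ho = 0; ho < Ho; ++ho) dxcol[ho / 2] += dycol[ho];
      }
    }
  }
  return dx;
}
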