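// Compiled kernels for the denoising networks and the rigid registration:
// 2-D convolution forward/backward via im2col + GEMM, and bilinear
// resampling under an affine (rigid + scale) map. Arrays follow R's
// column-major layout: images are (H, W, C, N), kernels are (k, k, Cin, F).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols) {
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const int ci = i + Ho * j;
      const int iy0 = i * stride - pad;
      const int ix0 = j * stride - pad;
      double* dst = cols.colptr(ci);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int dx = 0; dx < k; ++dx) {
          const int ix = ix0 + dx;
          const bool xin = (ix >= 0 && ix < W);
          for (int dy = 0; dy < k; ++dy) {
            const int iy = iy0 + dy;
            dst[dy + k * dx + k * k * c] =
              (xin && iy >= 0 && iy < H) ? xc[iy + (size_t)H * ix] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, NumericVector b,
                           int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int kkC = k * k * C;
  const int F = w.size() / kkC;
  arma::mat wm(w.begin(), kkC, F, false, true);
  arma::rowvec bv(b.begin(), F);
  NumericVector out((size_t)Ho * Wo * F * N);
  arma::mat cols(kkC, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat y = cols.t() * wm;          // (Ho*Wo, F)
    y.each_row() += bv;
    std::copy(y.begin(), y.end(), out.begin() + (size_t)Ho * Wo * F * n);
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim,
                  NumericVector w, NumericVector dy,
                  int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int kkC = k * k * C;
  const int F = w.size() / kkC;
  arma::mat wm(w.begin(), kkC, F, false, true);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dW(kkC, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat cols(kkC, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)H * W * C * n;
    im2col(xp, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat dym((double*)(dy.begin() + (size_t)Ho * Wo * F * n),
                  (size_t)Ho * Wo, F, false, true);
    dW += cols * dym;
    db += arma::sum(dym, 0).t();
    arma::mat dcols = wm * dym.t();       // (kkC, Ho*Wo)
    double* dxp = dx.begin() + (size_t)H * W * C * n;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int ci = i + Ho * j;
        const int iy0 = i * stride - pad;
        const int ix0 = j * stride - pad;
        const double* src = dcols.colptr(ci);
        for (int c = 0; c < C; ++c) {
          double* dxc = dxp + (size_t)H * W * c;
          for (int dxk = 0; dxk < k; ++dxk) {
            const int ix = ix0 + dxk;
            if (ix < 0 || ix >= W) continue;
            for (int dyk = 0; dyk < k; ++dyk) {
              const int iy = iy0 + dyk;
              if (iy < 0 || iy >= H) continue;
              dxc[iy + (size_t)H * ix] += src[dyk + k * dxk + k * k * c];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = IntegerVector::create(k, k, C, F);
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Bilinear resampling: output pixel q = (row, col) (0-based) samples the
// source image at p = A[,1:2] %*% q + A[,3]; samples outside the source
// domain are filled with 0.
// [[Rcpp::export]]
NumericMatrix cpp_resample_affine(NumericMatrix img, NumericMatrix A) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  const double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  for (int qc = 0; qc < W; ++qc) {
    for (int qr = 0; qr < H; ++qr) {
      const double pr = a11 * qr + a12 * qc + a13;
      const double pc = a21 * qr + a22 * qc + a23;
      if (pr < -1.0 || pr > H || pc < -1.0 || pc > W) continue;
      const int r0 = (int)std::floor(pr), c0 = (int)std::floor(pc);
      const double fr = pr - r0, fc = pc - c0;
      double v = 0.0;
      for (int dc = 0; dc <= 1; ++dc) {
        const int cc = c0 + dc;
        if (cc < 0 || cc >= W) continue;
        const double wc = dc ? fc : 1.0 - fc;
        for (int dr = 0; dr <= 1; ++dr) {
          const int rr = r0 + dr;
          if (rr < 0 || rr >= H) continue;
          const double wr = dr ? fr : 1.0 - fr;
          v += wr * wc * img(rr, cc);
        }
      }
      out(qr, qc) = v;
    }
  }
  return out;
}
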