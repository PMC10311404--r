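// Fused "combined layer" of the window classifier: 3x3 same-padding
// convolution (im2col + BLAS sgemm), ReLU, and max-pooling of size 2 along
// the SNP (width) axis with Keras-style valid semantics (odd trailing
// column dropped). Ties in the pool pick the left element.
//
// Arithmetic is single precision internally (the usual choice for CNN
// training); parameters and activations cross the R boundary as doubles.
//
// Layouts (column-major, matching R arrays):
//   activations X: (H, W, C, B)
//   kernels K:     (3, 3, C, F), flattened to a (9C x F) matrix
//   patches P:     (H*W*B x 9C), row index h + H*w + H*W*b,
//                  column index di + 3*dj + 9*c
//
// For backpropagation the forward pass stores, per pooled element, a code:
// 0 = gradient flows to the left pre-pool column, 1 = to the right one,
// 2 = winner was non-positive (ReLU cut, no gradient).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fmat im2col3(const double* X, int H, int W, int C, int B) {
  arma::fmat P((size_t)H * W * B, 9 * C, arma::fill::none);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        float* col = P.colptr(di + 3 * dj + 9 * c);
        int h0 = std::max(0, 1 - di), h1 = std::min(H, H + 1 - di);
        for (int b = 0; b < B; ++b) {
          const double* Xb = X + ((size_t)b * C + c) * H * W;
          float* colb = col + (size_t)b * H * W;
          for (int w = 0; w < W; ++w) {
            int ws = w + dj - 1;
            float* dst = colb + (size_t)w * H;
            if (ws < 0 || ws >= W) {
              std::fill(dst, dst + H, 0.0f);
              continue;
            }
            const double* src = Xb + (size_t)ws * H + (di - 1);
            if (h0 > 0) dst[0] = 0.0f;
            for (int h = h0; h < h1; ++h) dst[h] = (float)src[h];
            if (h1 < H) dst[H - 1] = 0.0f;
          }
        }
      }
    }
  }
  return P;
}

static arma::fmat to_f(const double* x, size_t n, size_t m) {
  arma::fmat out(n, m, arma::fill::none);
  float* o = out.memptr();
  for (size_t i = 0; i < n * m; ++i) o[i] = (float)x[i];
  return out;
}

// float patches travel back to R as raw bytes
static RawVector pack_fmat(const arma::fmat& P) {
  RawVector rv((R_xlen_t)P.n_elem * sizeof(float));
  std::memcpy(RAW(rv), P.memptr(), P.n_elem * sizeof(float));
  rv.attr("pdim") = IntegerVector::create(P.n_rows, P.n_cols);
  return rv;
}

// [[Rcpp::export(name = ".conv_block_forward_cpp")]]
List conv_block_forward_cpp(NumericVector X, NumericVector K,
                            NumericVector bias, bool keep) {
  IntegerVector xd = X.attr("dim"), kd = K.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3], F = kd[3];
  if (W < 2) stop("input width %d cannot be pooled below 1", W);
  int W2 = W / 2;
  arma::fmat P = im2col3(REAL(X), H, W, C, B);
  arma::fmat Km = to_f(REAL(K), 9 * C, F);
  arma::fmat Y = P * Km;
  arma::frowvec bf(F);
  for (int f = 0; f < F; ++f) bf[f] = (float)REAL(bias)[f];
  Y.each_row() += bf;

  NumericVector out((R_xlen_t)H * W2 * F * B);
  out.attr("dim") = IntegerVector::create(H, W2, F, B);
  double* o = REAL(out);
  RawVector code(keep ? (R_xlen_t)H * W2 * F * B : 0);
  unsigned char* cp = keep ? RAW(code) : nullptr;

  for (int f = 0; f < F; ++f) {
    const float* yc = Y.colptr(f);
    for (int b = 0; b < B; ++b) {
      const float* yb = yc + (size_t)b * H * W;
      double* ob = o + ((size_t)b * F + f) * H * W2;
      unsigned char* cb = cp ? cp + ((size_t)b * F + f) * H * W2 : nullptr;
      for (int w2 = 0; w2 < W2; ++w2) {
        const float* a = yb + (size_t)(2 * w2) * H;
        const float* r = a + H;
        double* od = ob + (size_t)w2 * H;
        for (int h = 0; h < H; ++h) {
          float av = a[h] > 0 ? a[h] : 0.0f;
          float rv = r[h] > 0 ? r[h] : 0.0f;
          if (av >= rv) {
            od[h] = av;
            if (cb) cb[(size_t)w2 * H + h] = av > 0 ? 0 : 2;
          } else {
            od[h] = rv;
            if (cb) cb[(size_t)w2 * H + h] = 1;
          }
        }
      }
    }
  }
  List res = List::create(Named("out") = out);
  if (keep) {
    res["patches"] = pack_fmat(P);
    res["code"] = code;
  }
  return res;
}

// [[Rcpp::export(name = ".conv_block_backward_cpp")]]
List conv_block_backward_cpp(NumericVector dOut, RawVector code,
                             RawVector P, NumericVector K,
                             IntegerVector xdim) {
  IntegerVector kd = K.attr("dim");
  IntegerVector pd = P.attr("pdim");
  int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3], F = kd[3];
  int W2 = W / 2;
  const double* dp = REAL(dOut);
  const unsigned char* cp = RAW(code);

  // un-pool + un-ReLU into the (H*W*B x F) gradient of the pre-activations
  arma::fmat dY((size_t)H * W * B, F, arma::fill::zeros);
  for (int f = 0; f < F; ++f) {
    float* yc = dY.colptr(f);
    for (int b = 0; b < B; ++b) {
      const double* db = dp + ((size_t)b * F + f) * H * W2;
      const unsigned char* cb = cp + ((size_t)b * F + f) * H * W2;
      float* yb = yc + (size_t)b * H * W;
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h = 0; h < H; ++h) {
          unsigned char cd = cb[(size_t)w2 * H + h];
          if (cd == 2) continue;
          yb[(size_t)(2 * w2 + cd) * H + h] =
              (float)db[(size_t)w2 * H + h];
        }
      }
    }
  }

  const arma::fmat Pm((float*)RAW(P), pd[0], pd[1], false, true);
  arma::fmat Km = to_f(REAL(K), 9 * C, F);
  arma::fmat dK = Pm.t() * dY;
  arma::frowvec dbias = arma::sum(dY, 0);
  arma::fmat dP = dY * Km.t();

  NumericVector dX((R_xlen_t)H * W * C * B);
  dX.attr("dim") = IntegerVector::create(H, W, C, B);
  std::fill(REAL(dX), REAL(dX) + dX.size(), 0.0);
  double* o = REAL(dX);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const float* col = dP.colptr(di + 3 * dj + 9 * c);
        int h0 = std::max(0, 1 - di), h1 = std::min(H, H + 1 - di);
        if (h1 <= h0) continue;
        for (int b = 0; b < B; ++b) {
          double* Ob = o + ((size_t)b * C + c) * H * W;
          const float* colb = col + (size_t)b * H * W;
          for (int w = 0; w < W; ++w) {
            int ws = w + dj - 1;
            if (ws < 0 || ws >= W) continue;
            double* dst = Ob + (size_t)ws * H + (h0 + di - 1);
            const float* src = colb + (size_t)w * H + h0;
            for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  NumericVector dKv((R_xlen_t)dK.n_elem);
  for (size_t i = 0; i < dK.n_elem; ++i) REAL(dKv)[i] = dK.memptr()[i];
  dKv.attr("dim") = kd;
  NumericVector dbv(F);
  for (int f = 0; f < F; ++f) dbv[f] = dbias[f];
  return List::create(Named("dX") = dX, Named("dK") = dKv,
                      Named("db") = dbv);
}
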