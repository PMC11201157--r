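#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensors are flat numeric vectors in (H, W, N, C) column-major layout.
// im2col for a 3x3 same-padding convolution: returns the (H*W*N) x (9*C)
// patch matrix whose product with a (9*C) x Cout weight matrix yields the
// convolution output as an (H*W*N) x Cout matrix.

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericVector& x, int H, int W, int N, int C) {
  const size_t rows = (size_t)H * W * N;
  NumericMatrix p(rows, 9 * C);
  const double* xp = x.begin();
  double* pp = p.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int k = di + 3 * dj;
        const int h0 = std::max(0, 1 - di), h1 = std::min(H, H + 1 - di);
        double* col = pp + rows * (k * C + c);
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + (size_t)H * W * (n + (size_t)N * c);
          double* outn = col + (size_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj - 1;
            double* out = outn + (size_t)H * w;
            if (sw < 0 || sw >= W) {
              std::memset(out, 0, sizeof(double) * H);
              continue;
            }
            const double* src = xc + (size_t)H * sw + (di - 1);
            if (h0 > 0) out[0] = 0.0;
            std::memcpy(out + h0, src + h0, sizeof(double) * (h1 - h0));
            if (h1 < H) out[H - 1] = 0.0;
          }
        }
      }
    }
  }
  return p;
}

// Adjoint of im2col3: scatter-add patch-matrix gradients back to the
// (H, W, N, C) input gradient.

// [[Rcpp::export]]
NumericVector col2im3(const NumericMatrix& dp, int H, int W, int N, int C) {
  const size_t rows = (size_t)H * W * N;
  NumericVector dx(rows * C);
  double* dxp = dx.begin();
  const double* pp = dp.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int k = di + 3 * dj;
        const int h0 = std::max(0, 1 - di), h1 = std::min(H, H + 1 - di);
        const double* col = pp + rows * (k * C + c);
        for (int n = 0; n < N; ++n) {
          double* xc = dxp + (size_t)H * W * (n + (size_t)N * c);
          const double* inn = col + (size_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj - 1;
            if (sw < 0 || sw >= W) continue;
            double* dst = xc + (size_t)H * sw + (di - 1);
            const double* src = inn + (size_t)H * w;
            for (int h = h0; h < h1; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// 2x2 max pooling with argmax bookkeeping, and its adjoint.

// [[Rcpp::export]]
List pool2_fwd(const NumericVector& x, int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const size_t no = (size_t)Ho * Wo * N * C;
  NumericVector y(no);
  IntegerVector arg(no);
  const double* xp = x.begin();
  for (size_t q = 0; q < (size_t)N * C; ++q) {
    const double* xs = xp + (size_t)H * W * q;
    double* ys = y.begin() + (size_t)Ho * Wo * q;
    int* as = arg.begin() + (size_t)Ho * Wo * q;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int base = 2 * h + H * 2 * w;
        const int cand[4] = {base, base + 1, base + H, base + H + 1};
        int best = 0;
        double bv = xs[cand[0]];
        for (int k = 1; k < 4; ++k) {
          if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = k; }
        }
        ys[h + Ho * w] = bv;
        as[h + Ho * w] = cand[best];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["out"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector pool2_bwd(const NumericVector& dy, const IntegerVector& arg,
                        int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * N * C);
  for (size_t q = 0; q < (size_t)N * C; ++q) {
    const double* ds = dy.begin() + (size_t)Ho * Wo * q;
    const int* as = arg.begin() + (size_t)Ho * Wo * q;
    double* xs = dx.begin() + (size_t)H * W * q;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) xs[as[i]] += ds[i];
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// Batch-norm column kernels: normalize and scale/shift in one pass, and the
// corresponding input-gradient combination.

// [[Rcpp::export]]
List bn_apply(const NumericMatrix& xm, const NumericVector& mu,
              const NumericVector& istd, const NumericVector& gamma,
              const NumericVector& beta) {
  const size_t n = xm.nrow();
  const int C = xm.ncol();
  NumericMatrix xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    const double* src = xm.begin() + n * c;
    double* xh = xhat.begin() + n * c;
    double* yy = y.begin() + n * c;
    for (size_t i = 0; i < n; ++i) {
      const double v = (src[i] - m) * is;
      xh[i] = v;
      yy[i] = g * v + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// [[Rcpp::export]]
NumericMatrix bn_input_grad(const NumericMatrix& dym,
                            const NumericMatrix& xhat,
                            const NumericVector& gamma,
                            const NumericVector& istd,
                            const NumericVector& s1,
                            const NumericVector& s2) {
  const size_t n = dym.nrow();
  const int C = dym.ncol();
  NumericMatrix dx(n, C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], is = istd[c];
    const double a1 = s1[c] / n, a2 = s2[c] / n;
    const double* dy = dym.begin() + n * c;
    const double* xh = xhat.begin() + n * c;
    double* out = dx.begin() + n * c;
    for (size_t i = 0; i < n; ++i) {
      out[i] = (g * dy[i] - a1 - xh[i] * a2) * is;
    }
  }
  return dx;
}

// Elementwise activations and their derivatives (0 = ReLU, 1 = GELU,
// 2 = Swish), evaluated in C to avoid repeated large temporaries.

// [[Rcpp::export]]
NumericVector act_eval(const NumericVector& x, int kind, bool deriv) {
  const size_t n = x.size();
  NumericVector out(n);
  const double* xp = x.begin();
  double* op = out.begin();
  const double inv_sqrt2 = 0.7071067811865475244;
  const double inv_sqrt2pi = 0.3989422804014326779;
  if (kind == 0) {
    if (!deriv) for (size_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
    else for (size_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? 1.0 : 0.0;
  } else if (kind == 1) {
    for (size_t i = 0; i < n; ++i) {
      const double phi = 0.5 * std::erfc(-xp[i] * inv_sqrt2);
      if (!deriv) op[i] = xp[i] * phi;
      else op[i] = phi + xp[i] * inv_sqrt2pi * std::exp(-0.5 * xp[i] * xp[i]);
    }
  } else {
    for (size_t i = 0; i < n; ++i) {
      const double s = 1.0 / (1.0 + std::exp(-xp[i]));
      if (!deriv) op[i] = xp[i] * s;
      else op[i] = s * (1.0 + xp[i] * (1.0 - s));
    }
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// Row-wise max and (first) argmax of a matrix, for stabilized softmax and
// hard predictions.

// [[Rcpp::export]]
List row_max(const NumericMatrix& x) {
  const size_t n = x.nrow();
  const int C = x.ncol();
  NumericVector mx(n);
  IntegerVector arg(n);
  for (size_t i = 0; i < n; ++i) { mx[i] = x(i, 0); arg[i] = 0; }
  for (int c = 1; c < C; ++c) {
    const double* col = x.begin() + n * c;
    for (size_t i = 0; i < n; ++i) {
      if (col[i] > mx[i]) { mx[i] = col[i]; arg[i] = c; }
    }
  }
  return List::create(_["max"] = mx, _["arg"] = arg);
}

// In-place im2col into a preallocated (H*W*N) x (9*C) buffer, so the large
// patch matrices are reused across training iterations instead of being
// reallocated (allocator churn dominates runtime otherwise).

// [[Rcpp::export]]
void im2col3_into(const NumericVector& x, int H, int W, int N, int C,
                  NumericMatrix p) {
  const size_t rows = (size_t)H * W * N;
  if ((size_t)p.nrow() != rows || p.ncol() != 9 * C)
    stop("im2col3_into: buffer shape mismatch");
  const double* xp = x.begin();
  double* pp = p.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int k = di + 3 * dj;
        const int h0 = std::max(0, 1 - di), h1 = std::min(H, H + 1 - di);
        double* col = pp + rows * (k * C + c);
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + (size_t)H * W * (n + (size_t)N * c);
          double* outn = col + (size_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj - 1;
            double* out = outn + (size_t)H * w;
            if (sw < 0 || sw >= W) {
              std::memset(out, 0, sizeof(double) * H);
              continue;
            }
            const double* src = xc + (size_t)H * sw + (di - 1);
            if (h0 > 0) out[0] = 0.0;
            std::memcpy(out + h0, src + h0, sizeof(double) * (h1 - h0));
            if (h1 < H) out[H - 1] = 0.0;
          }
        }
      }
    }
  }
}
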