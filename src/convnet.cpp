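// Dense 3x3x3 convolution, 2x2x2 max-pooling and x2 trilinear upsampling
// for 5-D activation arrays laid out as (X, Y, Z, C, N) in R's column-major
// order. Convolution uses im2col + BLAS (via Armadillo) with zero padding 1
// and stride 1, chunked along z to bound the scratch matrix. Backward passes
// are exact adjoints/gradients of the forward passes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill M (X*Y*(z1-z0) x 27*Cin) with the 3x3x3 neighbourhoods of sample
// block xn for output slices [z0, z1). Out-of-range taps are written as 0
// inline (M is not pre-cleared).
template <typename MatT, typename ElemT>
static void im2col_chunk(const double* xn, int X, int Y, int Z, int Cin,
                         int z0, int z1, MatT& M) {
  const size_t plane = (size_t)X * Y;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = xn + (size_t)c * plane * Z;
    for (int dz = 0; dz < 3; ++dz)
      for (int dy = 0; dy < 3; ++dy)
        for (int dx = 0; dx < 3; ++dx) {
          const int col = (dx + 3 * (dy + 3 * dz)) + 27 * c;
          ElemT* Mcol = M.colptr(col);
          const int x_lo = std::max(0, 1 - dx);
          const int x_hi = std::min(X, X + 1 - dx);
          for (int iz = z0; iz < z1; ++iz) {
            const int sz = iz + dz - 1;
            ElemT* Mz = Mcol + (size_t)(iz - z0) * plane;
            if (sz < 0 || sz >= Z) {
              std::fill(Mz, Mz + plane, (ElemT)0);
              continue;
            }
            for (int iy = 0; iy < Y; ++iy) {
              const int sy = iy + dy - 1;
              ElemT* dst = Mz + (size_t)iy * X;
              if (sy < 0 || sy >= Y) {
                std::fill(dst, dst + X, (ElemT)0);
                continue;
              }
              const double* src = xc + ((size_t)sz * Y + sy) * X + (dx - 1);
              for (int ix = 0; ix < x_lo; ++ix) dst[ix] = (ElemT)0;
              for (int ix = x_lo; ix < x_hi; ++ix) dst[ix] = (ElemT)src[ix];
              for (int ix = x_hi; ix < X; ++ix) dst[ix] = (ElemT)0;
            }
          }
        }
  }
}

static int chunk_slices(int X, int Y, int Cin) {
  // cap the im2col scratch at ~160 MB of doubles
  double maxv = 2.0e7 / (27.0 * Cin * (double)X * Y);
  int zc = (int)maxv;
  return std::max(1, zc);
}

// Large convolutions run in float32 (half the memory traffic, sgemm);
// small ones stay in double so gradient checks hold to fine tolerances.
static bool use_float32(int X, int Y, int Z, int Cin, int N) {
  return 27.0 * X * Y * (double)Z * Cin * N > 4.0e6;
}

template <typename MatT, typename ElemT>
static void conv3d_fw_impl(const double* x, int X, int Y, int Z, int Cin,
                           int N, const double* Wp, const double* b,
                           int Cout, double* out) {
  const size_t plane = (size_t)X * Y, svol = plane * Z;
  MatT Wm(27 * Cin, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < 27 * Cin; ++i)
      Wm(i, j) = (ElemT)Wp[i + (size_t)j * 27 * Cin];
  const int Zc = chunk_slices(X, Y, Cin);
  MatT M(plane * std::min(Zc, Z), 27 * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * svol * Cin;
    double* on = out + (size_t)n * svol * Cout;
    for (int z0 = 0; z0 < Z; z0 += Zc) {
      const int z1 = std::min(Z, z0 + Zc);
      const size_t Vc = plane * (z1 - z0);
      if (M.n_rows != Vc) M.set_size(Vc, 27 * Cin);
      im2col_chunk<MatT, ElemT>(xn, X, Y, Z, Cin, z0, z1, M);
      MatT O = M * Wm;
      for (int co = 0; co < Cout; ++co) {
        double* dst = on + (size_t)co * svol + (size_t)z0 * plane;
        const ElemT* src = O.colptr(co);
        const double bc = b[co];
        for (size_t i = 0; i < Vc; ++i) dst[i] = (double)src[i] + bc;
      }
    }
  }
}

template <typename MatT, typename ElemT>
static void conv3d_dw_impl(const double* x, int X, int Y, int Z, int Cin,
                           int N, const double* dout, int Cout,
                           arma::mat& dW, arma::vec& db) {
  const size_t plane = (size_t)X * Y, svol = plane * Z;
  const int Zc = chunk_slices(X, Y, Cin);
  MatT M(plane * std::min(Zc, Z), 27 * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * svol * Cin;
    const double* gn = dout + (size_t)n * svol * Cout;
    for (int z0 = 0; z0 < Z; z0 += Zc) {
      const int z1 = std::min(Z, z0 + Zc);
      const size_t Vc = plane * (z1 - z0);
      if (M.n_rows != Vc) M.set_size(Vc, 27 * Cin);
      MatT G(Vc, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* src = gn + (size_t)co * svol + (size_t)z0 * plane;
        ElemT* gcol = G.colptr(co);
        double acc = 0.0;
        for (size_t i = 0; i < Vc; ++i) { gcol[i] = (ElemT)src[i]; acc += src[i]; }
        db[co] += acc;
      }
      im2col_chunk<MatT, ElemT>(xn, X, Y, Z, Cin, z0, z1, M);
      dW += arma::conv_to<arma::mat>::from(M.t() * G);
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, IntegerVector xdim,
                        NumericMatrix W, NumericVector b) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3], N = xdim[4];
  const int Cout = W.ncol();
  if (W.nrow() != 27 * Cin) stop("weight matrix must have 27*Cin rows");
  const size_t svol = (size_t)X * Y * Z;
  NumericVector out((R_xlen_t)svol * Cout * N);
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout, N);
  if (use_float32(X, Y, Z, Cin, N))
    conv3d_fw_impl<arma::fmat, float>(x.begin(), X, Y, Z, Cin, N, W.begin(),
                                      b.begin(), Cout, out.begin());
  else
    conv3d_fw_impl<arma::mat, double>(x.begin(), X, Y, Z, Cin, N, W.begin(),
                                      b.begin(), Cout, out.begin());
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, IntegerVector xdim,
               NumericMatrix W, NumericVector dout) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3], N = xdim[4];
  const int Cout = W.ncol();
  arma::mat dW(27 * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  if (use_float32(X, Y, Z, Cin, N))
    conv3d_dw_impl<arma::fmat, float>(x.begin(), X, Y, Z, Cin, N,
                                      dout.begin(), Cout, dW, db);
  else
    conv3d_dw_impl<arma::mat, double>(x.begin(), X, Y, Z, Cin, N,
                                      dout.begin(), Cout, dW, db);
  // dx as a convolution of dout with the spatially flipped, transposed
  // kernel: dx[:, ci] = sum_o dout[shift -o] W[o, ci, :]
  NumericMatrix Wt(27 * Cout, Cin);
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int o = 0; o < 27; ++o)
        Wt(26 - o + 27 * co, ci) = W(o + 27 * ci, co);
  IntegerVector gdim = IntegerVector::create(X, Y, Z, Cout, N);
  NumericVector zb(Cin);
  NumericVector dx = conv3d_fw(dout, gdim, Wt, zb);
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = wrap(db));
}

// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool3d needs even spatial dims");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const size_t svol = (size_t)X * Y * Z;
  R_xlen_t olen = (R_xlen_t)Xo * Yo * Zo * C * N;
  NumericVector out(olen);
  IntegerVector amax(olen);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xb = x.begin() + ((size_t)n * C + c) * svol;
      const size_t base = ((size_t)n * C + c) * svol;
      for (int kz = 0; kz < Zo; ++kz)
        for (int ky = 0; ky < Yo; ++ky)
          for (int kx = 0; kx < Xo; ++kx, ++o) {
            double best = R_NegInf; size_t bi = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  size_t idx = (size_t)(2 * kx + dx) +
                    (size_t)X * ((2 * ky + dy) + (size_t)Y * (2 * kz + dz));
                  double v = xb[idx];
                  if (v > best) { best = v; bi = idx; }
                }
            out[o] = best;
            amax[o] = (int)(base + bi);  // global index into x
          }
    }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(NumericVector dout, IntegerVector argmax,
                           IntegerVector xdim) {
  R_xlen_t xlen = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector dx(xlen);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i]] += dout[i];
  return dx;
}

// trilinear x2 upsampling weights for one axis (align_corners = FALSE):
// output centre i maps to source coordinate i/2 - 0.25, edge-clamped
static void up_weights(int L, std::vector<int>& i0, std::vector<double>& w1) {
  i0.resize(2 * L); w1.resize(2 * L);
  for (int i = 0; i < 2 * L; ++i) {
    double s = 0.5 * i - 0.25;
    if (s < 0) s = 0;
    if (s > L - 1) s = L - 1;
    int a = (int)std::floor(s);
    if (a > L - 2) a = std::max(0, L - 2);
    i0[i] = a;
    w1[i] = (L == 1) ? 0.0 : s - a;
  }
}

// [[Rcpp::export]]
NumericVector upsample3d_fw(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  std::vector<int> ix0, iy0, iz0; std::vector<double> wx, wy, wz;
  up_weights(X, ix0, wx); up_weights(Y, iy0, wy); up_weights(Z, iz0, wz);
  const size_t svol = (size_t)X * Y * Z;
  NumericVector out((R_xlen_t)8 * svol * C * N);
  out.attr("dim") = IntegerVector::create(2 * X, 2 * Y, 2 * Z, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xb = x.begin() + ((size_t)n * C + c) * svol;
      for (int k = 0; k < 2 * Z; ++k) {
        const int z0 = iz0[k]; const double cz = wz[k];
        for (int j = 0; j < 2 * Y; ++j) {
          const int y0 = iy0[j]; const double cy = wy[j];
          for (int i = 0; i < 2 * X; ++i, ++o) {
            const int x0 = ix0[i]; const double cx = wx[i];
            const int x1 = std::min(x0 + 1, X - 1);
            const int y1 = std::min(y0 + 1, Y - 1);
            const int z1 = std::min(z0 + 1, Z - 1);
            #define AT(a,b,cc) xb[(size_t)(a) + (size_t)X * ((b) + (size_t)Y * (cc))]
            double v =
              (1-cz)*((1-cy)*((1-cx)*AT(x0,y0,z0) + cx*AT(x1,y0,z0)) +
                         cy *((1-cx)*AT(x0,y1,z0) + cx*AT(x1,y1,z0))) +
                 cz *((1-cy)*((1-cx)*AT(x0,y0,z1) + cx*AT(x1,y0,z1)) +
                         cy *((1-cx)*AT(x0,y1,z1) + cx*AT(x1,y1,z1)));
            #undef AT
            out[o] = v;
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample3d_bw(NumericVector dout, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  std::vector<int> ix0, iy0, iz0; std::vector<double> wx, wy, wz;
  up_weights(X, ix0, wx); up_weights(Y, iy0, wy); up_weights(Z, iz0, wz);
  const size_t svol = (size_t)X * Y * Z;
  NumericVector dx((R_xlen_t)svol * C * N);
  dx.attr("dim") = xdim;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xb = dx.begin() + ((size_t)n * C + c) * svol;
      for (int k = 0; k < 2 * Z; ++k) {
        const int z0 = iz0[k]; const double cz = wz[k];
        for (int j = 0; j < 2 * Y; ++j) {
          const int y0 = iy0[j]; const double cy = wy[j];
          for (int i = 0; i < 2 * X; ++i, ++o) {
            const int x0 = ix0[i]; const double cx = wx[i];
            const int x1 = std::min(x0 + 1, X - 1);
            const int y1 = std::min(y0 + 1, Y - 1);
            const int z1 = std::min(z0 + 1, Z - 1);
            const double g = dout[o];
            #define AT(a,b,cc) xb[(size_t)(a) + (size_t)X * ((b) + (size_t)Y * (cc))]
            AT(x0,y0,z0) += g*(1-cz)*(1-cy)*(1-cx);
            AT(x1,y0,z0) += g*(1-cz)*(1-cy)*cx;
            AT(x0,y1,z0) += g*(1-cz)*cy*(1-cx);
            AT(x1,y1,z0) += g*(1-cz)*cy*cx;
            AT(x0,y0,z1) += g*cz*(1-cy)*(1-cx);
            AT(x1,y0,z1) += g*cz*(1-cy)*cx;
            AT(x0,y1,z1) += g*cz*cy*(1-cx);
            AT(x1,y1,z1) += g*cz*cy*cx;
            #undef AT
          }
        }
      }
    }
  return dx;
}
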