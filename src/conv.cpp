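// Valid (unpadded) 3-D convolution kernels via im2col + GEMM.
// Tensors are R arrays in column-major order:
//   feature maps  [X, Y, Z, C]
//   conv weights  [kx, ky, kz, Cin, Cout]
// The 2-D network is the kz = 1, Z = 1 special case of the same code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(arma::uword i, arma::uword j, arma::uword k,
                               arma::uword c, arma::uword X, arma::uword Y,
                               arma::uword Z) {
  return i + X * (j + Y * (k + Z * c));
}

// Fill the im2col matrix (N x K, N = ox*oy output voxels of slice oz,
// K = kx*ky*kz*Cin) for one output z-slice. Row-contiguous copies along x.
static void im2col_slice(const double* x, arma::mat& col, arma::uword oz,
                         arma::uword X, arma::uword Y, arma::uword Z,
                         arma::uword Cin, arma::uword kx, arma::uword ky,
                         arma::uword kz, arma::uword ox, arma::uword oy) {
  arma::uword krow = 0;
  for (arma::uword c = 0; c < Cin; ++c)
    for (arma::uword iz = 0; iz < kz; ++iz)
      for (arma::uword iy = 0; iy < ky; ++iy)
        for (arma::uword ix = 0; ix < kx; ++ix, ++krow) {
          double* dst = col.colptr(krow);
          for (arma::uword j = 0; j < oy; ++j) {
            const double* src = x + idx4(ix, j + iy, oz + iz, c, X, Y, Z);
            std::copy(src, src + ox, dst + (arma::uword)ox * j);
          }
        }
}

// [[Rcpp::export]]
NumericVector conv3d_valid_forward(NumericVector x, NumericVector w,
                                   NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  const arma::uword kx = wd[0], ky = wd[1], kz = wd[2], Cout = wd[4];
  if ((arma::uword)wd[3] != Cin) stop("conv: channel mismatch");
  if (X < kx || Y < ky || Z < kz) stop("conv: input smaller than kernel");
  const arma::uword ox = X - kx + 1, oy = Y - ky + 1, oz = Z - kz + 1;
  const arma::uword N = ox * oy, K = kx * ky * kz * Cin;

  NumericVector out(ox * oy * oz * Cout);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, Cout);
  arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(N, K);
  for (arma::uword z = 0; z < oz; ++z) {
    im2col_slice(x.begin(), col, z, X, Y, Z, Cin, kx, ky, kz, ox, oy);
    arma::mat res = col * W;  // N x Cout
    for (arma::uword c = 0; c < Cout; ++c) {
      double* dst = out.begin() + idx4(0, 0, z, c, ox, oy, oz);
      const double* src = res.colptr(c);
      const double bc = b[c];
      for (arma::uword n = 0; n < N; ++n) dst[n] = src[n] + bc;
    }
  }
  return out;
}

// Gradients of the valid convolution. Returns list(dx, dw, db).
// [[Rcpp::export]]
List conv3d_valid_backward(NumericVector x, NumericVector w,
                           NumericVector dout) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  const arma::uword kx = wd[0], ky = wd[1], kz = wd[2], Cout = wd[4];
  const arma::uword ox = X - kx + 1, oy = Y - ky + 1, oz = Z - kz + 1;
  const arma::uword N = ox * oy, K = kx * ky * kz * Cin;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dW(dw.begin(), K, Cout, false, true);
  arma::mat col(N, K), dOutN(N, Cout);

  for (arma::uword z = 0; z < oz; ++z) {
    for (arma::uword c = 0; c < Cout; ++c) {
      const double* src = dout.begin() + idx4(0, 0, z, c, ox, oy, oz);
      std::copy(src, src + N, dOutN.colptr(c));
      db[c] += std::accumulate(src, src + N, 0.0);
    }
    im2col_slice(x.begin(), col, z, X, Y, Z, Cin, kx, ky, kz, ox, oy);
    dW += col.t() * dOutN;                   // K x Cout
    arma::mat dCol = dOutN * W.t();          // N x K, scatter back (col2im)
    arma::uword krow = 0;
    for (arma::uword c = 0; c < Cin; ++c)
      for (arma::uword iz = 0; iz < kz; ++iz)
        for (arma::uword iy = 0; iy < ky; ++iy)
          for (arma::uword ix = 0; ix < kx; ++ix, ++krow) {
            const double* src = dCol.colptr(krow);
            for (arma::uword j = 0; j < oy; ++j) {
              double* dst = dx.begin() + idx4(ix, j + iy, z + iz, c, X, Y, Z);
              const double* s = src + (arma::uword)ox * j;
              for (arma::uword i = 0; i < ox; ++i) dst[i] += s[i];
            }
          }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max-pooling by per-axis factors p = (px, py, pz); extents must divide.
// Returns list(y, argmax) where argmax holds 1-based linear indices into x.
// [[Rcpp::export]]
List maxpool3d_forward(NumericVector x, IntegerVector p) {
  IntegerVector xd = x.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const arma::uword px = p[0], py = p[1], pz = p[2];
  if (X % px || Y % py || Z % pz) stop("pool: extent not divisible by factor");
  const arma::uword ox = X / px, oy = Y / py, oz = Z / pz;

  NumericVector y(ox * oy * oz * C);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  IntegerVector am(y.size());
  am.attr("dim") = y.attr("dim");

  arma::uword n = 0;
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword k = 0; k < oz; ++k)
      for (arma::uword j = 0; j < oy; ++j)
        for (arma::uword i = 0; i < ox; ++i, ++n) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bidx = 0;
          for (arma::uword dz = 0; dz < pz; ++dz)
            for (arma::uword dy = 0; dy < py; ++dy)
              for (arma::uword dx_ = 0; dx_ < px; ++dx_) {
                arma::uword ii = idx4(i * px + dx_, j * py + dy, k * pz + dz,
                                      c, X, Y, Z);
                if (x[ii] > best) { best = x[ii]; bidx = ii; }
              }
          y[n] = best;
          am[n] = (int)(bidx + 1);
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward(NumericVector dy, IntegerVector argmax,
                                 IntegerVector xdim) {
  NumericVector dx((arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t n = 0; n < dy.size(); ++n) dx[argmax[n] - 1] += dy[n];
  return dx;
}

// Nearest-neighbour upsampling by per-axis factors.
// [[Rcpp::export]]
NumericVector upsample3d_forward(NumericVector x, IntegerVector p) {
  IntegerVector xd = x.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const arma::uword px = p[0], py = p[1], pz = p[2];
  const arma::uword ox = X * px, oy = Y * py, oz = Z * pz;
  NumericVector y(ox * oy * oz * C);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword k = 0; k < oz; ++k)
      for (arma::uword j = 0; j < oy; ++j) {
        const double* src = x.begin() + idx4(0, j / py, k / pz, c, X, Y, Z);
        double* dst = y.begin() + idx4(0, j, k, c, ox, oy, oz);
        for (arma::uword i = 0; i < ox; ++i) dst[i] = src[i / px];
      }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample3d_backward(NumericVector dy, IntegerVector p,
                                  IntegerVector xdim) {
  const arma::uword X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const arma::uword px = p[0], py = p[1], pz = p[2];
  const arma::uword ox = X * px, oy = Y * py, oz = Z * pz;
  NumericVector dx((arma::uword)X * Y * Z * C);
  dx.attr("dim") = xdim;
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword k = 0; k < oz; ++k)
      for (arma::uword j = 0; j < oy; ++j) {
        const double* src = dy.begin() + idx4(0, j, k, c, ox, oy, oz);
        double* dst = dx.begin() + idx4(0, j / py, k / pz, c, X, Y, Z);
        for (arma::uword i = 0; i < ox; ++i) dst[i / px] += src[i];
      }
  return dx;
}
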