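// Batch-normalisation and ReLU kernels over minibatches (lists of
// [X, Y, Z, C] arrays). Channels are the slowest-varying dimension, so
// per-channel work runs over contiguous blocks.

#include <Rcpp.h>

using namespace Rcpp;

static inline R_xlen_t nvox_of(NumericVector x, int& C) {
  IntegerVector d = x.attr("dim");
  C = d[3];
  return (R_xlen_t)d[0] * d[1] * d[2];
}

// per-channel sums and sums of squares across batch and spatial dims
// [[Rcpp::export]]
List bn_stats_cpp(List xs) {
  int C = 0;
  double n = 0;
  NumericVector s, s2;
  for (int b = 0; b < xs.size(); ++b) {
    NumericVector x = xs[b];
    R_xlen_t nv = nvox_of(x, C);
    if (b == 0) { s = NumericVector(C); s2 = NumericVector(C); }
    n += (double)nv;
    const double* px = x.begin();
    for (int c = 0; c < C; ++c) {
      double a = 0, a2 = 0;
      const double* p = px + (R_xlen_t)c * nv;
      for (R_xlen_t i = 0; i < nv; ++i) { a += p[i]; a2 += p[i] * p[i]; }
      s[c] += a; s2[c] += a2;
    }
  }
  return List::create(_["sum"] = s, _["sum2"] = s2, _["n"] = n);
}

// normalise and scale: returns xhat and out = gamma * xhat + beta
// [[Rcpp::export]]
List bn_apply_cpp(List xs, NumericVector mu, NumericVector inv_sd,
                  NumericVector gamma, NumericVector beta) {
  List xhat(xs.size()), out(xs.size());
  for (int b = 0; b < xs.size(); ++b) {
    NumericVector x = xs[b];
    int C; R_xlen_t nv = nvox_of(x, C);
    NumericVector h(x.size()), o(x.size());
    h.attr("dim") = x.attr("dim");
    o.attr("dim") = x.attr("dim");
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], is = inv_sd[c], g = gamma[c], bt = beta[c];
      const double* p = x.begin() + (R_xlen_t)c * nv;
      double* ph = h.begin() + (R_xlen_t)c * nv;
      double* po = o.begin() + (R_xlen_t)c * nv;
      for (R_xlen_t i = 0; i < nv; ++i) {
        const double v = (p[i] - m) * is;
        ph[i] = v;
        po[i] = g * v + bt;
      }
    }
    xhat[b] = h; out[b] = o;
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// backward pass; train = FALSE treats BN as a fixed affine map
// [[Rcpp::export]]
List bn_bwd_cpp(List xhat, List douts, NumericVector gamma,
                NumericVector inv_sd, double n, bool train) {
  const int B = xhat.size();
  int C = 0;
  { NumericVector x0 = xhat[0]; nvox_of(x0, C); }
  NumericVector dgamma(C), dbeta(C);
  for (int b = 0; b < B; ++b) {
    NumericVector h = xhat[b], d = douts[b];
    int Cc; R_xlen_t nv = nvox_of(h, Cc);
    for (int c = 0; c < C; ++c) {
      const double* ph = h.begin() + (R_xlen_t)c * nv;
      const double* pd = d.begin() + (R_xlen_t)c * nv;
      double a = 0, g = 0;
      for (R_xlen_t i = 0; i < nv; ++i) { a += pd[i]; g += pd[i] * ph[i]; }
      dbeta[c] += a; dgamma[c] += g;
    }
  }
  List dxs(B);
  for (int b = 0; b < B; ++b) {
    NumericVector h = xhat[b], d = douts[b];
    int Cc; R_xlen_t nv = nvox_of(h, Cc);
    NumericVector dx(d.size());
    dx.attr("dim") = d.attr("dim");
    for (int c = 0; c < C; ++c) {
      const double* ph = h.begin() + (R_xlen_t)c * nv;
      const double* pd = d.begin() + (R_xlen_t)c * nv;
      double* px = dx.begin() + (R_xlen_t)c * nv;
      if (train) {
        const double scale = gamma[c] * inv_sd[c] / n;
        const double db = dbeta[c], dg = dgamma[c];
        for (R_xlen_t i = 0; i < nv; ++i)
          px[i] = scale * (n * pd[i] - db - ph[i] * dg);
      } else {
        const double scale = gamma[c] * inv_sd[c];
        for (R_xlen_t i = 0; i < nv; ++i) px[i] = scale * pd[i];
      }
    }
    dxs[b] = dx;
  }
  return List::create(_["dx"] = dxs, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List relu_fwd_cpp(List xs) {
  List out(xs.size());
  for (int b = 0; b < xs.size(); ++b) {
    NumericVector x = xs[b];
    NumericVector o = clone(x);
    for (R_xlen_t i = 0; i < o.size(); ++i) if (o[i] < 0) o[i] = 0;
    out[b] = o;
  }
  return out;
}

// [[Rcpp::export]]
List relu_bwd_cpp(List outs, List douts) {
  List dxs(outs.size());
  for (int b = 0; b < outs.size(); ++b) {
    NumericVector o = outs[b], d = douts[b];
    NumericVector dx = clone(d);
    for (R_xlen_t i = 0; i < dx.size(); ++i) if (o[i] <= 0) dx[i] = 0;
    dxs[b] = dx;
  }
  return dxs;
}
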