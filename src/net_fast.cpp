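// Single-precision fast path for the detection network's training loop.
//
// Mirrors the reference R implementation (R/net.R) layer for layer: a
// CSP-style backbone (c1..c6, residual at c3), FPN-style neck (lat3..5,
// nearest 2x upsampling, sm3..5) and per-level 1x1 heads. All activations
// and caches are held in float on the C++ side; parameters come in as an
// R list each call (they are small) and gradients go back as doubles.
// The R path remains the contract/reference; equivalence is tested.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float BN_EPS = 1e-5f;
static const float SLOPE = 0.1f;

struct ConvCache {
  fmat Xc;    // im2col'ed input (k=3) or the input itself (k=1)
  fmat xhat;  // normalised pre-scale activations
  fvec v;     // batch variance
  fvec mu;    // batch mean
  fmat Y;     // pre-activation (post-BN)
  int Hin, Win;
};

struct NetCache {
  int B, H, W;
  std::map<std::string, ConvCache> conv;
  std::map<std::string, fmat> act;  // named activations needed in backward
};

static fmat im2col_f(const fmat& X, int B, int H, int W, int stride) {
  const int C = X.n_rows;
  const int Ho = H / stride, Wo = W / stride;
  fmat out(C * 9, (size_t)B * Ho * Wo, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t in0 = (size_t)b * H * W;
    const size_t out0 = (size_t)b * Ho * Wo;
    for (int xo = 0; xo < Wo; ++xo)
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t oc = out0 + (size_t)xo * Ho + yo;
        const int xc = xo * stride, yc = yo * stride;
        for (int kx = 0; kx < 3; ++kx) {
          const int xi = xc + kx - 1;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int yi = yc + ky - 1;
            if (yi < 0 || yi >= H) continue;
            const float* src = X.colptr(in0 + (size_t)xi * H + yi);
            float* dst = out.colptr(oc) + kx * 3 + ky;
            for (int c = 0; c < C; ++c) dst[c * 9] = src[c];
          }
        }
      }
  }
  return out;
}

static fmat col2im_f(const fmat& dCol, int B, int H, int W, int stride) {
  const int C = dCol.n_rows / 9;
  const int Ho = H / stride, Wo = W / stride;
  fmat out(C, (size_t)B * H * W, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t in0 = (size_t)b * H * W;
    const size_t out0 = (size_t)b * Ho * Wo;
    for (int xo = 0; xo < Wo; ++xo)
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t oc = out0 + (size_t)xo * Ho + yo;
        const int xc = xo * stride, yc = yo * stride;
        for (int kx = 0; kx < 3; ++kx) {
          const int xi = xc + kx - 1;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int yi = yc + ky - 1;
            if (yi < 0 || yi >= H) continue;
            const float* src = dCol.colptr(oc) + kx * 3 + ky;
            float* dst = out.colptr(in0 + (size_t)xi * H + yi);
            for (int c = 0; c < C; ++c) dst[c] += src[c * 9];
          }
        }
      }
  }
  return out;
}

static fmat up2_f(const fmat& A, int B, int h, int w) {
  fmat out(A.n_rows, (size_t)B * 4 * h * w);
  for (int b = 0; b < B; ++b)
    for (int x = 0; x < 2 * w; ++x)
      for (int y = 0; y < 2 * h; ++y)
        out.col((size_t)b * 4 * h * w + (size_t)x * 2 * h + y) =
          A.col((size_t)b * h * w + (size_t)(x / 2) * h + y / 2);
  return out;
}

static fmat up2_adj_f(const fmat& dU, int B, int h, int w) {
  fmat out(dU.n_rows, (size_t)B * h * w, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int x = 0; x < 2 * w; ++x)
      for (int y = 0; y < 2 * h; ++y)
        out.col((size_t)b * h * w + (size_t)(x / 2) * h + y / 2) +=
          dU.col((size_t)b * 4 * h * w + (size_t)x * 2 * h + y);
  return out;
}

static fmat as_f(SEXP m) {
  Rcpp::NumericMatrix rm(m);
  fmat out(rm.nrow(), rm.ncol());
  const double* src = rm.begin();
  float* dst = out.memptr();
  const size_t n = (size_t)rm.nrow() * rm.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static fvec vec_f(SEXP v) {
  Rcpp::NumericVector rv(v);
  fvec out(rv.size());
  for (int i = 0; i < rv.size(); ++i) out[i] = (float)rv[i];
  return out;
}

static Rcpp::NumericMatrix as_d(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  const float* src = m.memptr();
  double* dst = out.begin();
  const size_t n = (size_t)m.n_rows * m.n_cols;
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// conv + batch-norm + leaky relu; caches for backward when train
static fmat conv_fwd_f(const List& p, const fmat& X, int B, int H, int W,
                       int k, int stride, bool train, NetCache* cache,
                       const std::string& name) {
  fmat W_ = as_f(p["W"]);
  fmat Xc = (k == 3) ? im2col_f(X, B, H, W, stride) : X;
  fmat Z = W_ * Xc;
  fvec gamma = vec_f(p["gamma"]), beta = vec_f(p["beta"]);
  fvec mu, v;
  if (train) {
    mu = mean(Z, 1);
    v = mean(square(Z), 1) - square(mu);
  } else {
    mu = vec_f(p["rmean"]);
    v = vec_f(p["rvar"]);
  }
  fmat xhat = Z;
  xhat.each_col() -= mu;
  fvec inv_sd = 1.0f / sqrt(v + BN_EPS);
  xhat.each_col() %= inv_sd;
  fmat Y = xhat;
  Y.each_col() %= gamma;
  Y.each_col() += beta;
  fmat A = Y;
  A.transform([](float y) { return y > 0 ? y : SLOPE * y; });
  if (cache) {
    ConvCache cc;
    cc.Xc = std::move(Xc); cc.xhat = std::move(xhat);
    cc.v = v; cc.mu = mu; cc.Y = std::move(Y);
    cc.Hin = H; cc.Win = W;
    cache->conv[name] = std::move(cc);
  }
  return A;
}

struct ConvGrad { fmat dX, dW; fvec dgamma, dbeta; };

static ConvGrad conv_bwd_f(const List& p, NetCache& cache,
                           const std::string& name, const fmat& dA,
                           int B, int k, int stride) {
  ConvCache& cc = cache.conv[name];
  fmat W_ = as_f(p["W"]);
  fvec gamma = vec_f(p["gamma"]);
  fmat dY = dA;
  {
    const fmat& Y = cc.Y;
    float* d = dY.memptr(); const float* y = Y.memptr();
    const size_t n = dY.n_elem;
    for (size_t i = 0; i < n; ++i) if (y[i] <= 0) d[i] *= SLOPE;
  }
  fvec dgamma = sum(dY % cc.xhat, 1);
  fvec dbeta = sum(dY, 1);
  fmat dxhat = dY;
  dxhat.each_col() %= gamma;
  fvec m1 = mean(dxhat, 1);
  fvec m2 = mean(dxhat % cc.xhat, 1);
  fmat dZ = dxhat;
  dZ.each_col() -= m1;
  dZ -= cc.xhat.each_col() % m2;
  fvec inv_sd = 1.0f / sqrt(cc.v + BN_EPS);
  dZ.each_col() %= inv_sd;
  ConvGrad g;
  g.dW = dZ * cc.Xc.t();
  fmat dXc = W_.t() * dZ;
  g.dX = (k == 3) ? col2im_f(dXc, B, cc.Hin, cc.Win, stride)
                  : std::move(dXc);
  g.dgamma = dgamma; g.dbeta = dbeta;
  return g;
}

// [[Rcpp::export]]
List net_fwd_fast(List params, Rcpp::NumericMatrix X0, int B, int H, int W,
                  bool train) {
  NetCache* cache = new NetCache();
  cache->B = B; cache->H = H; cache->W = W;
  fmat X = as_f(X0);
  fmat A1 = conv_fwd_f(params["c1"], X, B, H, W, 3, 2, train, cache, "c1");
  int H2 = H / 2, W2 = W / 2;
  fmat A2 = conv_fwd_f(params["c2"], A1, B, H2, W2, 3, 2, train, cache, "c2");
  int H4 = H2 / 2, W4 = W2 / 2;
  fmat A3r = conv_fwd_f(params["c3"], A2, B, H4, W4, 3, 1, train, cache,
                        "c3");
  fmat A3 = A2 + A3r;
  fmat C3 = conv_fwd_f(params["c4"], A3, B, H4, W4, 3, 2, train, cache,
                       "c4");
  int H8 = H4 / 2, W8 = W4 / 2;
  fmat C4 = conv_fwd_f(params["c5"], C3, B, H8, W8, 3, 2, train, cache,
                       "c5");
  int H16 = H8 / 2, W16 = W8 / 2;
  fmat C5 = conv_fwd_f(params["c6"], C4, B, H16, W16, 3, 2, train, cache,
                       "c6");
  int H32 = H16 / 2, W32 = W16 / 2;
  fmat G5 = conv_fwd_f(params["lat5"], C5, B, H32, W32, 1, 1, train, cache,
                       "lat5");
  fmat G4 = conv_fwd_f(params["lat4"], C4, B, H16, W16, 1, 1, train, cache,
                       "lat4");
  fmat G3 = conv_fwd_f(params["lat3"], C3, B, H8, W8, 1, 1, train, cache,
                       "lat3");
  fmat P4 = G4 + up2_f(G5, B, H32, W32);
  fmat P3 = G3 + up2_f(P4, B, H16, W16);
  fmat S5 = conv_fwd_f(params["sm5"], G5, B, H32, W32, 3, 1, train, cache,
                       "sm5");
  fmat S4 = conv_fwd_f(params["sm4"], P4, B, H16, W16, 3, 1, train, cache,
                       "sm4");
  fmat S3 = conv_fwd_f(params["sm3"], P3, B, H8, W8, 3, 1, train, cache,
                       "sm3");
  List h3 = params["h3"], h4 = params["h4"], h5 = params["h5"];
  fmat H3m = as_f(h3["W"]) * S3; H3m.each_col() += vec_f(h3["b"]);
  fmat H4m = as_f(h4["W"]) * S4; H4m.each_col() += vec_f(h4["b"]);
  fmat H5m = as_f(h5["W"]) * S5; H5m.each_col() += vec_f(h5["b"]);
  if (train) {
    cache->act["S3"] = std::move(S3);
    cache->act["S4"] = std::move(S4);
    cache->act["S5"] = std::move(S5);
    // BN batch statistics for the running-stat update in R
    List stats;
    const char* nm[] = {"c1", "c2", "c3", "c4", "c5", "c6", "lat3", "lat4",
                        "lat5", "sm3", "sm4", "sm5"};
    for (int i = 0; i < 12; ++i) {
      ConvCache& cc = cache->conv[nm[i]];
      stats[nm[i]] = List::create(
        Named("mu") = Rcpp::NumericVector(cc.mu.begin(), cc.mu.end()),
        Named("v") = Rcpp::NumericVector(cc.v.begin(), cc.v.end()));
    }
    Rcpp::XPtr<NetCache> ptr(cache, true);
    return List::create(Named("H3") = as_d(H3m), Named("H4") = as_d(H4m),
                        Named("H5") = as_d(H5m), Named("cache") = ptr,
                        Named("stats") = stats);
  }
  delete cache;
  return List::create(Named("H3") = as_d(H3m), Named("H4") = as_d(H4m),
                      Named("H5") = as_d(H5m));
}

// [[Rcpp::export]]
List net_bwd_fast(List params, SEXP cache_ptr, Rcpp::NumericMatrix dH3,
                  Rcpp::NumericMatrix dH4, Rcpp::NumericMatrix dH5) {
  Rcpp::XPtr<NetCache> cache(cache_ptr);
  int B = cache->B, H = cache->H, W = cache->W;
  int H4d = H / 4, W4d = W / 4, H8 = H / 8, W8 = W / 8;
  int H16 = H / 16, W16 = W / 16, H32 = H / 32, W32 = W / 32;
  fmat d3 = as_f(dH3), d4 = as_f(dH4), d5 = as_f(dH5);
  List h3 = params["h3"], h4 = params["h4"], h5 = params["h5"];
  List out;
  out["h3"] = List::create(Named("W") = as_d(d3 * cache->act["S3"].t()),
                           Named("b") = as_d(fmat(sum(d3, 1))));
  out["h4"] = List::create(Named("W") = as_d(d4 * cache->act["S4"].t()),
                           Named("b") = as_d(fmat(sum(d4, 1))));
  out["h5"] = List::create(Named("W") = as_d(d5 * cache->act["S5"].t()),
                           Named("b") = as_d(fmat(sum(d5, 1))));
  fmat dS3 = as_f(h3["W"]).t() * d3;
  fmat dS4 = as_f(h4["W"]).t() * d4;
  fmat dS5 = as_f(h5["W"]).t() * d5;
  auto pack = [&out](const std::string& n, ConvGrad& g) {
    out[n] = List::create(
      Named("dW") = as_d(g.dW),
      Named("dgamma") = Rcpp::NumericVector(g.dgamma.begin(), g.dgamma.end()),
      Named("dbeta") = Rcpp::NumericVector(g.dbeta.begin(), g.dbeta.end()));
  };
  ConvGrad gsm3 = conv_bwd_f(params["sm3"], *cache, "sm3", dS3, B, 3, 1);
  ConvGrad gsm4 = conv_bwd_f(params["sm4"], *cache, "sm4", dS4, B, 3, 1);
  ConvGrad gsm5 = conv_bwd_f(params["sm5"], *cache, "sm5", dS5, B, 3, 1);
  pack("sm3", gsm3); pack("sm4", gsm4); pack("sm5", gsm5);
  fmat dP3 = gsm3.dX;
  fmat dP4 = gsm4.dX + up2_adj_f(dP3, B, H16, W16);
  fmat dG5 = gsm5.dX + up2_adj_f(dP4, B, H32, W32);
  ConvGrad gl3 = conv_bwd_f(params["lat3"], *cache, "lat3", dP3, B, 1, 1);
  ConvGrad gl4 = conv_bwd_f(params["lat4"], *cache, "lat4", dP4, B, 1, 1);
  ConvGrad gl5 = conv_bwd_f(params["lat5"], *cache, "lat5", dG5, B, 1, 1);
  pack("lat3", gl3); pack("lat4", gl4); pack("lat5", gl5);
  ConvGrad g6 = conv_bwd_f(params["c6"], *cache, "c6", gl5.dX, B, 3, 2);
  pack("c6", g6);
  fmat dC4 = gl4.dX + g6.dX;
  ConvGrad g5 = conv_bwd_f(params["c5"], *cache, "c5", dC4, B, 3, 2);
  pack("c5", g5);
  fmat dC3 = gl3.dX + g5.dX;
  ConvGrad g4 = conv_bwd_f(params["c4"], *cache, "c4", dC3, B, 3, 2);
  pack("c4", g4);
  ConvGrad g3 = conv_bwd_f(params["c3"], *cache, "c3", g4.dX, B, 3, 1);
  pack("c3", g3);
  fmat dA2 = g4.dX + g3.dX;
  ConvGrad g2 = conv_bwd_f(params["c2"], *cache, "c2", dA2, B, 3, 2);
  pack("c2", g2);
  ConvGrad g1 = conv_bwd_f(params["c1"], *cache, "c1", g2.dX, B, 3, 2);
  pack("c1", g1);
  return out;
}
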