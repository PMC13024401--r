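// Fused transformer-encoder forward/backward for the training fast path.
//
// The whole encoder stack runs here in single precision: per-layer QKV
// projections, multi-head scaled dot-product attention, residual + layer
// norm, and the position-wise feed-forward sublayer. Intermediate
// activations stay on the C++ side in an external-pointer cache between the
// forward and backward calls, so nothing but the layer input and output
// crosses into R. Dropout masks are drawn from R's RNG (seed-reproducible).
//
// The R implementation of the same maps (double precision, used when
// getOption("ecgrhythm.attn_double") is set) is the reference these kernels
// are tested against.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;

static const float LN_EPS = 1e-5f;

struct LayerCache {
  fmat X0, Q, K, V, O, xhat1, X1, H, xhat2, dm1, dm2;
  fvec inv1, inv2;
};

struct EncoderCache {
  std::vector<LayerCache> layers;
};

static fmat softmax_rows_f(fmat S) {
  S.each_col() -= arma::max(S, 1);
  fmat E = arma::exp(S);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

static void attn_fwd(const fmat& Q, const fmat& K, const fmat& V, fmat& O,
                     int B, int W, int H, int dk) {
  const float scale = 1.0f / std::sqrt(static_cast<float>(dk));
  for (int b = 0; b < B; ++b) {
    arma::span rows(b * W, b * W + W - 1);
    for (int h = 0; h < H; ++h) {
      arma::span cols(h * dk, h * dk + dk - 1);
      fmat A = softmax_rows_f(Q(rows, cols) * K(rows, cols).t() * scale);
      O(rows, cols) = A * V(rows, cols);
    }
  }
}

static void attn_bwd(const fmat& Q, const fmat& K, const fmat& V,
                     const fmat& dO, fmat& dQ, fmat& dK, fmat& dV,
                     int B, int W, int H, int dk) {
  const float scale = 1.0f / std::sqrt(static_cast<float>(dk));
  for (int b = 0; b < B; ++b) {
    arma::span rows(b * W, b * W + W - 1);
    for (int h = 0; h < H; ++h) {
      arma::span cols(h * dk, h * dk + dk - 1);
      fmat Qh = Q(rows, cols), Kh = K(rows, cols), Vh = V(rows, cols);
      fmat A = softmax_rows_f(Qh * Kh.t() * scale);
      fmat dOh = dO(rows, cols);
      dV(rows, cols) = A.t() * dOh;
      fmat dS = A % (dOh * Vh.t());
      fmat Ar = A;
      Ar.each_col() %= arma::sum(dS, 1);
      dS -= Ar;
      dS *= scale;
      dQ(rows, cols) = dS * Kh;
      dK(rows, cols) = dS.t() * Qh;
    }
  }
}

// LayerNorm over rows; returns normalized output, keeps xhat and 1/sd.
static fmat ln_fwd(const fmat& X, const fvec& g, const fvec& b,
                   fmat& xhat, fvec& inv) {
  fvec mu = arma::mean(X, 1);
  fmat Xc = X.each_col() - mu;
  inv = 1.0f / arma::sqrt(arma::mean(arma::square(Xc), 1) + LN_EPS);
  xhat = Xc.each_col() % inv;
  fmat out = xhat.each_row() % g.t();
  out.each_row() += b.t();
  return out;
}

static fmat ln_bwd(const fmat& dout, const fmat& xhat, const fvec& inv,
                   const fvec& g, fvec& dgamma, fvec& dbeta) {
  dgamma = arma::sum(dout % xhat, 0).t();
  dbeta = arma::sum(dout, 0).t();
  fmat dxhat = dout.each_row() % g.t();
  fvec m1 = arma::mean(dxhat, 1);
  fvec m2 = arma::mean(dxhat % xhat, 1);
  fmat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  return dx;
}

// Inverted dropout mask. Drawing millions of deviates through the R RNG API
// is prohibitively slow, so a local 64-bit generator is seeded from R's RNG
// stream once per forward pass: runs remain a pure function of set.seed().
static fmat draw_mask(int n, int m, double p, std::mt19937_64& gen) {
  fmat M(n, m);
  const float scale = 1.0f / (1.0f - static_cast<float>(p));
  const double inv = 1.0 / 9007199254740992.0;  // 2^-53
  float* ptr = M.memptr();
  const arma::uword total = M.n_elem;
  for (arma::uword i = 0; i < total; ++i) {
    double u = static_cast<double>(gen() >> 11) * inv;
    ptr[i] = (u >= p) ? scale : 0.0f;
  }
  return M;
}

static std::mt19937_64 seed_from_r_rng() {
  const uint64_t lo = static_cast<uint64_t>(unif_rand() * 4294967296.0);
  const uint64_t hi = static_cast<uint64_t>(unif_rand() * 4294967296.0);
  return std::mt19937_64((hi << 32) ^ lo);
}

static fvec as_fvec(SEXP x) {
  NumericVector v(x);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = static_cast<float>(v[i]);
  return out;
}

static fmat as_fmat(SEXP x) {
  NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = static_cast<float>(m(i, j));
  return out;
}

// [[Rcpp::export(name = ".encoder_forward_cpp")]]
List encoder_forward_cpp(const arma::mat& X_in, List layers, double drop_p,
                         int B, int W, int H, int dk, bool keep) {
  fmat X = arma::conv_to<fmat>::from(X_in);
  const int n_layers = layers.size();
  XPtr<EncoderCache> cache(new EncoderCache(), true);
  if (keep) cache->layers.resize(n_layers);
  std::mt19937_64 gen;
  if (drop_p > 0) gen = seed_from_r_rng();
  for (int l = 0; l < n_layers; ++l) {
    List ly = layers[l];
    fmat Wq = as_fmat(ly["Wq"]), Wk = as_fmat(ly["Wk"]),
        Wv = as_fmat(ly["Wv"]), Wo = as_fmat(ly["Wo"]);
    fvec bq = as_fvec(ly["bq"]), bk = as_fvec(ly["bk"]),
        bv = as_fvec(ly["bv"]), bo = as_fvec(ly["bo"]);
    fvec ln1_g = as_fvec(ly["ln1_g"]), ln1_b = as_fvec(ly["ln1_b"]);
    fvec ln2_g = as_fvec(ly["ln2_g"]), ln2_b = as_fvec(ly["ln2_b"]);
    fmat W1 = as_fmat(ly["W1"]), W2 = as_fmat(ly["W2"]);
    fvec b1 = as_fvec(ly["b1"]), b2 = as_fvec(ly["b2"]);

    fmat Q = X * Wq; Q.each_row() += bq.t();
    fmat K = X * Wk; K.each_row() += bk.t();
    fmat V = X * Wv; V.each_row() += bv.t();
    fmat O(Q.n_rows, Q.n_cols);
    attn_fwd(Q, K, V, O, B, W, H, dk);
    fmat M = O * Wo; M.each_row() += bo.t();
    fmat dm1, dm2;
    if (drop_p > 0) { dm1 = draw_mask(M.n_rows, M.n_cols, drop_p, gen); M %= dm1; }
    fmat R1 = X + M;
    fmat xhat1; fvec inv1;
    fmat X1 = ln_fwd(R1, ln1_g, ln1_b, xhat1, inv1);
    fmat Hh = X1 * W1; Hh.each_row() += b1.t();
    Hh.elem(arma::find(Hh < 0)).zeros();
    fmat Fo = Hh * W2; Fo.each_row() += b2.t();
    if (drop_p > 0) { dm2 = draw_mask(Fo.n_rows, Fo.n_cols, drop_p, gen); Fo %= dm2; }
    fmat R2 = X1 + Fo;
    fmat xhat2; fvec inv2;
    fmat out = ln_fwd(R2, ln2_g, ln2_b, xhat2, inv2);
    if (keep) {
      LayerCache& cc = cache->layers[l];
      cc.X0 = std::move(X); cc.Q = std::move(Q); cc.K = std::move(K);
      cc.V = std::move(V); cc.O = std::move(O);
      cc.xhat1 = std::move(xhat1); cc.inv1 = std::move(inv1);
      cc.X1 = std::move(X1); cc.H = std::move(Hh);
      cc.xhat2 = std::move(xhat2); cc.inv2 = std::move(inv2);
      cc.dm1 = std::move(dm1); cc.dm2 = std::move(dm2);
    }
    X = std::move(out);
  }
  return List::create(_["out"] = arma::conv_to<arma::mat>::from(X),
                      _["cache"] = cache);
}

// [[Rcpp::export(name = ".encoder_backward_cpp")]]
List encoder_backward_cpp(const arma::mat& dX_in, List layers, SEXP cache_ptr,
                          int B, int W, int H, int dk) {
  XPtr<EncoderCache> cache(cache_ptr);
  fmat dX = arma::conv_to<fmat>::from(dX_in);
  const int n_layers = layers.size();
  List grads(n_layers);
  for (int l = n_layers - 1; l >= 0; --l) {
    List ly = layers[l];
    LayerCache& cc = cache->layers[l];
    fmat Wq = as_fmat(ly["Wq"]), Wk = as_fmat(ly["Wk"]),
        Wv = as_fmat(ly["Wv"]), Wo = as_fmat(ly["Wo"]);
    fvec ln1_g = as_fvec(ly["ln1_g"]), ln2_g = as_fvec(ly["ln2_g"]);
    fmat W1 = as_fmat(ly["W1"]), W2 = as_fmat(ly["W2"]);

    fvec gln2_g, gln2_b;
    fmat dR2 = ln_bwd(dX, cc.xhat2, cc.inv2, ln2_g, gln2_g, gln2_b);
    fmat dFo = (cc.dm2.n_elem > 0) ? fmat(dR2 % cc.dm2) : dR2;
    fmat gW2 = cc.H.t() * dFo;
    fvec gb2 = arma::sum(dFo, 0).t();
    fmat dHpre = dFo * W2.t();
    dHpre.elem(arma::find(cc.H <= 0)).zeros();
    fmat gW1 = cc.X1.t() * dHpre;
    fvec gb1 = arma::sum(dHpre, 0).t();
    fmat dX1 = dR2 + dHpre * W1.t();
    fvec gln1_g, gln1_b;
    fmat dR1 = ln_bwd(dX1, cc.xhat1, cc.inv1, ln1_g, gln1_g, gln1_b);
    fmat dM = (cc.dm1.n_elem > 0) ? fmat(dR1 % cc.dm1) : dR1;
    fmat gWo = cc.O.t() * dM;
    fvec gbo = arma::sum(dM, 0).t();
    fmat dO = dM * Wo.t();
    fmat dQ(cc.Q.n_rows, cc.Q.n_cols), dK(cc.K.n_rows, cc.K.n_cols),
        dV(cc.V.n_rows, cc.V.n_cols);
    attn_bwd(cc.Q, cc.K, cc.V, dO, dQ, dK, dV, B, W, H, dk);
    fmat gWq = cc.X0.t() * dQ;
    fmat gWk = cc.X0.t() * dK;
    fmat gWv = cc.X0.t() * dV;
    fvec gbq = arma::sum(dQ, 0).t();
    fvec gbk = arma::sum(dK, 0).t();
    fvec gbv = arma::sum(dV, 0).t();
    dX = dR1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();

    grads[l] = List::create(
        _["Wq"] = arma::conv_to<arma::mat>::from(gWq),
        _["bq"] = arma::conv_to<arma::vec>::from(gbq),
        _["Wk"] = arma::conv_to<arma::mat>::from(gWk),
        _["bk"] = arma::conv_to<arma::vec>::from(gbk),
        _["Wv"] = arma::conv_to<arma::mat>::from(gWv),
        _["bv"] = arma::conv_to<arma::vec>::from(gbv),
        _["Wo"] = arma::conv_to<arma::mat>::from(gWo),
        _["bo"] = arma::conv_to<arma::vec>::from(gbo),
        _["ln1_g"] = arma::conv_to<arma::vec>::from(gln1_g),
        _["ln1_b"] = arma::conv_to<arma::vec>::from(gln1_b),
        _["W1"] = arma::conv_to<arma::mat>::from(gW1),
        _["b1"] = arma::conv_to<arma::vec>::from(gb1),
        _["W2"] = arma::conv_to<arma::mat>::from(gW2),
        _["b2"] = arma::conv_to<arma::vec>::from(gb2),
        _["ln2_g"] = arma::conv_to<arma::vec>::from(gln2_g),
        _["ln2_b"] = arma::conv_to<arma::vec>::from(gln2_b));
  }
  return List::create(_["dX0"] = arma::conv_to<arma::mat>::from(dX),
                      _["grads"] = grads);
}
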