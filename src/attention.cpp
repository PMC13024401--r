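// Batched multi-head scaled dot-product attention kernels.
//
// Windows are stacked as B row-blocks of W positions; heads occupy
// contiguous column blocks of width dk. The O(W^2) score/weight matrices
// are formed head-by-head here and never cross into R, which keeps the
// training loop's memory flat and avoids interpreter overhead on the
// innermost loop.
//
// Arithmetic runs in single precision by default: attention scores are O(10)
// after layer normalization, so float mantissas are ample, and sgemm roughly
// doubles throughput on these small matrices. A double-precision path is
// kept for verification (finite-difference gradient checks).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

template <typename MT>
static MT softmax_rows(MT S) {
  S.each_col() -= arma::max(S, 1);
  MT E = arma::exp(S);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

template <typename MT>
static MT attn_forward_t(const MT& Q, const MT& K, const MT& V,
                         int B, int W, int H, int dk) {
  MT O(Q.n_rows, Q.n_cols);
  const double scale = 1.0 / std::sqrt(static_cast<double>(dk));
  for (int b = 0; b < B; ++b) {
    arma::span rows(b * W, b * W + W - 1);
    for (int h = 0; h < H; ++h) {
      arma::span cols(h * dk, h * dk + dk - 1);
      MT A = softmax_rows<MT>(Q(rows, cols) * K(rows, cols).t() * scale);
      O(rows, cols) = A * V(rows, cols);
    }
  }
  return O;
}

// Gradients of the attention output w.r.t. Q, K, V; softmax weights are
// recomputed from Q and K (cheaper than caching B*H W x W matrices).
template <typename MT>
static void attn_backward_t(const MT& Q, const MT& K, const MT& V,
                            const MT& dO, int B, int W, int H, int dk,
                            MT& dQ, MT& dK, MT& dV) {
  const double scale = 1.0 / std::sqrt(static_cast<double>(dk));
  for (int b = 0; b < B; ++b) {
    arma::span rows(b * W, b * W + W - 1);
    for (int h = 0; h < H; ++h) {
      arma::span cols(h * dk, h * dk + dk - 1);
      MT Qh = Q(rows, cols), Kh = K(rows, cols), Vh = V(rows, cols);
      MT A = softmax_rows<MT>(Qh * Kh.t() * scale);
      MT dOh = dO(rows, cols);
      dV(rows, cols) = A.t() * dOh;
      // dS = A % (dA - rowSums(dA % A)); fold in the 1/sqrt(dk) scale
      MT dS = A % (dOh * Vh.t());
      MT Ar = A;
      Ar.each_col() %= arma::sum(dS, 1);
      dS -= Ar;
      dS *= scale;
      dQ(rows, cols) = dS * Kh;
      dK(rows, cols) = dS.t() * Qh;
    }
  }
}

// [[Rcpp::export(name = ".attn_forward_cpp")]]
arma::mat attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                           const arma::mat& V, int B, int W, int H, int dk,
                           bool single_prec = true) {
  if (!single_prec) return attn_forward_t<arma::mat>(Q, K, V, B, W, H, dk);
  arma::fmat Qf = arma::conv_to<arma::fmat>::from(Q);
  arma::fmat Kf = arma::conv_to<arma::fmat>::from(K);
  arma::fmat Vf = arma::conv_to<arma::fmat>::from(V);
  return arma::conv_to<arma::mat>::from(
      attn_forward_t<arma::fmat>(Qf, Kf, Vf, B, W, H, dk));
}

// [[Rcpp::export(name = ".attn_backward_cpp")]]
List attn_backward_cpp(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::mat& dO,
                       int B, int W, int H, int dk,
                       bool single_prec = true) {
  if (!single_prec) {
    arma::mat dQ(Q.n_rows, Q.n_cols), dK(K.n_rows, K.n_cols),
        dV(V.n_rows, V.n_cols);
    attn_backward_t<arma::mat>(Q, K, V, dO, B, W, H, dk, dQ, dK, dV);
    return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
  }
  arma::fmat Qf = arma::conv_to<arma::fmat>::from(Q);
  arma::fmat Kf = arma::conv_to<arma::fmat>::from(K);
  arma::fmat Vf = arma::conv_to<arma::fmat>::from(V);
  arma::fmat dOf = arma::conv_to<arma::fmat>::from(dO);
  arma::fmat dQ(Qf.n_rows, Qf.n_cols), dK(Kf.n_rows, Kf.n_cols),
      dV(Vf.n_rows, Vf.n_cols);
  attn_backward_t<arma::fmat>(Qf, Kf, Vf, dOf, B, W, H, dk, dQ, dK, dV);
  return List::create(_["dQ"] = arma::conv_to<arma::mat>::from(dQ),
                      _["dK"] = arma::conv_to<arma::mat>::from(dK),
                      _["dV"] = arma::conv_to<arma::mat>::from(dV));
}
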