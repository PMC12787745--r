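// Compiled kernels for the multi-head self-attention block and the GELU
// activation. Sequences are stacked row-wise as (sample-major) blocks of
// T rows; attention runs independently per sample and head. These loops
// dominate training time in pure R, so they live here; their gradients
// are pinned against finite differences in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Q, K, V: (B*T) x d matrices, heads split d into nh contiguous slices.
// Returns O = softmax(Q K^T / sqrt(dh)) V per block, plus the attention
// weights P (T x T x nh*B) for the backward pass.
// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, int T, int nh) {
  const int N = Q.n_rows, d = Q.n_cols;
  const int B = N / T, dh = d / nh;
  const double sc = 1.0 / std::sqrt((double) dh);
  arma::mat O(N, d, arma::fill::zeros);
  arma::cube P(T, T, (size_t) nh * B);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T, r1 = r0 + T - 1;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat S = Q.submat(r0, c0, r1, c1) *
                    K.submat(r0, c0, r1, c1).t() * sc;
      S.each_col() -= arma::max(S, 1);
      arma::mat E = arma::exp(S);
      E.each_col() /= arma::sum(E, 1);
      P.slice((size_t) b * nh + h) = E;
      O.submat(r0, c0, r1, c1) = E * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(Named("O") = O, Named("P") = P);
}

// [[Rcpp::export]]
List attn_backward_cpp(const arma::cube& P, const arma::mat& dO,
                       const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, int T, int nh) {
  const int N = Q.n_rows, d = Q.n_cols;
  const int B = N / T, dh = d / nh;
  const double sc = 1.0 / std::sqrt((double) dh);
  arma::mat dQ(N, d, arma::fill::zeros), dK(N, d, arma::fill::zeros),
            dV(N, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T, r1 = r0 + T - 1;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      const arma::mat& Pm = P.slice((size_t) b * nh + h);
      arma::mat dOh = dO.submat(r0, c0, r1, c1);
      dV.submat(r0, c0, r1, c1) = Pm.t() * dOh;
      arma::mat dP = dOh * V.submat(r0, c0, r1, c1).t();
      arma::vec rs = arma::sum(Pm % dP, 1);
      dP.each_col() -= rs;
      arma::mat dS = Pm % dP;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) * sc;
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) * sc;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}

// tanh-approximation GELU; returns the activation and the tanh term so the
// backward pass can reuse it.
// [[Rcpp::export]]
List gelu_forward_cpp(const arma::mat& X) {
  const double c = 0.7978845608028654; // sqrt(2/pi)
  arma::mat U = arma::tanh(c * (X + 0.044715 * arma::pow(X, 3)));
  arma::mat Y = 0.5 * X % (1.0 + U);
  return List::create(Named("Y") = Y, Named("U") = U);
}

// [[Rcpp::export]]
arma::mat gelu_backward_cpp(const arma::mat& X, const arma::mat& U,
                            const arma::mat& dY) {
  const double c = 0.7978845608028654;
  arma::mat dydx = 0.5 * (1.0 + U) +
    0.5 * X % (1.0 - U % U) % (c * (1.0 + 3 * 0.044715 * X % X));
  return dY % dydx;
}
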