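// Fused 1D convolution block (same-padding conv, batch normalization,
// ReLU, 1x2 max pooling on time) for the sip-volume CNN.
//
// Batched activations are sample-major: a (B*L) x C matrix whose rows
// b*L .. b*L+L-1 hold sample b.  Kernel size is fixed at 5 (padding 2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int K = 5;
static const int PAD = 2;

// [[Rcpp::export]]
List sq_conv_block_fwd(const arma::mat& X, int B, int L, const arma::mat& W,
                       const arma::vec& bias, const arma::vec& gamma,
                       const arma::vec& beta, const arma::vec& rm,
                       const arma::vec& rv, bool training, double momentum,
                       double eps) {
  const int Cin = X.n_cols, Cout = W.n_cols;
  arma::mat Z(B * (size_t)L, Cout, arma::fill::zeros);
  arma::mat Xpad(L + 2 * PAD, Cin);
  for (int b = 0; b < B; ++b) {
    Xpad.zeros();
    Xpad.rows(PAD, PAD + L - 1) = X.rows(b * (size_t)L, b * (size_t)L + L - 1);
    arma::mat Zb(L, Cout, arma::fill::zeros);
    for (int k = 0; k < K; ++k)
      Zb += Xpad.rows(k, k + L - 1) * W.rows(k * Cin, k * Cin + Cin - 1);
    Z.rows(b * (size_t)L, b * (size_t)L + L - 1) = Zb;
  }
  Z.each_row() += bias.t();

  arma::rowvec m, v;
  arma::vec newRm = rm, newRv = rv;
  if (training) {
    m = arma::mean(Z, 0);
    v = arma::mean(arma::square(Z), 0) - arma::square(m);
    newRm = (1.0 - momentum) * rm + momentum * m.t();
    newRv = (1.0 - momentum) * rv + momentum * v.t();
  } else {
    m = rm.t();
    v = rv.t();
  }
  arma::rowvec inv = 1.0 / arma::sqrt(v + eps);
  arma::mat Zn = Z;
  Zn.each_row() -= m;
  Zn.each_row() %= inv;

  // ReLU(gamma*Zn + beta), then 1x2 max pool on time
  const int Lh = L / 2;
  arma::mat P(B * (size_t)Lh, Cout);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lh; ++t) {
      const size_t r1 = b * (size_t)L + 2 * t, r2 = r1 + 1;
      const size_t ro = b * (size_t)Lh + t;
      for (int c = 0; c < Cout; ++c) {
        double a1 = gamma[c] * Zn(r1, c) + beta[c];
        double a2 = gamma[c] * Zn(r2, c) + beta[c];
        if (a1 < 0) a1 = 0;
        if (a2 < 0) a2 = 0;
        P(ro, c) = a1 >= a2 ? a1 : a2;
      }
    }
  }
  return List::create(_["P"] = P, _["Zn"] = Zn, _["inv"] = inv.t(),
                      _["rm"] = newRm, _["rv"] = newRv);
}

// [[Rcpp::export]]
List sq_conv_block_bwd(const arma::mat& dP, const arma::mat& X,
                       const arma::mat& Zn, const arma::vec& inv,
                       const arma::vec& gamma, const arma::vec& beta,
                       const arma::mat& W, int B, int L) {
  const int Cin = X.n_cols, Cout = W.n_cols;
  const int Lh = L / 2;
  const size_t n = B * (size_t)L;

  // un-pool and un-ReLU: recompute activations from Zn
  arma::mat dY(n, Cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lh; ++t) {
      const size_t r1 = b * (size_t)L + 2 * t, r2 = r1 + 1;
      const size_t ro = b * (size_t)Lh + t;
      for (int c = 0; c < Cout; ++c) {
        double y1 = gamma[c] * Zn(r1, c) + beta[c];
        double y2 = gamma[c] * Zn(r2, c) + beta[c];
        double a1 = y1 > 0 ? y1 : 0, a2 = y2 > 0 ? y2 : 0;
        if (a1 >= a2) {
          if (y1 > 0) dY(r1, c) = dP(ro, c);
        } else {
          if (y2 > 0) dY(r2, c) = dP(ro, c);
        }
      }
    }
  }

  // batch-normalization backward
  arma::vec dgamma = arma::sum(dY % Zn, 0).t();
  arma::vec dbeta = arma::sum(dY, 0).t();
  arma::mat dZn = dY;
  dZn.each_row() %= gamma.t();
  arma::rowvec m1 = arma::mean(dZn, 0);
  arma::rowvec m2 = arma::mean(dZn % Zn, 0);
  arma::mat dZ = dZn;
  dZ.each_row() -= m1;
  dZ -= Zn.each_row() % m2;
  dZ.each_row() %= inv.t();

  // convolution backward
  arma::vec db = arma::sum(dZ, 0).t();
  arma::mat dW(K * Cin, Cout, arma::fill::zeros);
  arma::mat dX(n, Cin, arma::fill::zeros);
  arma::mat Xpad(L + 2 * PAD, Cin);
  arma::mat dXpad(L + 2 * PAD, Cin);
  for (int b = 0; b < B; ++b) {
    Xpad.zeros();
    Xpad.rows(PAD, PAD + L - 1) = X.rows(b * (size_t)L, b * (size_t)L + L - 1);
    const arma::mat dZb = dZ.rows(b * (size_t)L, b * (size_t)L + L - 1);
    dXpad.zeros();
    for (int k = 0; k < K; ++k) {
      dW.rows(k * Cin, k * Cin + Cin - 1) +=
        Xpad.rows(k, k + L - 1).t() * dZb;
      dXpad.rows(k, k + L - 1) +=
        dZb * W.rows(k * Cin, k * Cin + Cin - 1).t();
    }
    dX.rows(b * (size_t)L, b * (size_t)L + L - 1) =
      dXpad.rows(PAD, PAD + L - 1);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
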