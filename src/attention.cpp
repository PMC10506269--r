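// Inner loops of batched multi-head self-attention. Batches are row-blocked
// matrices (row r = position t + b*L); the attention matrices of all
// (head, sample) pairs are stacked row-wise in A, block (h, b) occupying
// rows h*L*B + b*L .. h*L*B + (b+1)*L - 1.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List mha_fwd_cpp(const arma::mat& Qa, const arma::mat& Ka,
                       const arma::mat& Va, int n_heads, int d_k, int d_h,
                       int L, int B) {
  const int dv = n_heads * d_h;
  mat A(static_cast<uword>(L) * B * n_heads, L);
  mat Hc(static_cast<uword>(L) * B, dv);
  const double sc = std::sqrt(static_cast<double>(d_k));
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L, r1 = r0 + L - 1;
    for (int h = 0; h < n_heads; ++h) {
      const int q0 = h * d_k, q1 = q0 + d_k - 1;
      const int v0 = h * d_h, v1 = v0 + d_h - 1;
      mat S = Qa.submat(r0, q0, r1, q1) * Ka.submat(r0, q0, r1, q1).t() / sc;
      S.each_col() -= max(S, 1);          // stable row softmax
      S = exp(S);
      S.each_col() /= sum(S, 1);
      const int a0 = h * L * B + r0;
      A.rows(a0, a0 + L - 1) = S;
      Hc.submat(r0, v0, r1, v1) = S * Va.submat(r0, v0, r1, v1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("Hc") = Hc);
}

// [[Rcpp::export]]
Rcpp::List mha_bwd_cpp(const arma::mat& A, const arma::mat& Qa,
                       const arma::mat& Ka, const arma::mat& Va,
                       const arma::mat& dHc, int n_heads, int d_k, int d_h,
                       int L, int B) {
  mat dQa(size(Qa), fill::zeros);
  mat dKa(size(Ka), fill::zeros);
  mat dVa(size(Va), fill::zeros);
  const double sc = std::sqrt(static_cast<double>(d_k));
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L, r1 = r0 + L - 1;
    for (int h = 0; h < n_heads; ++h) {
      const int q0 = h * d_k, q1 = q0 + d_k - 1;
      const int v0 = h * d_h, v1 = v0 + d_h - 1;
      const int a0 = h * L * B + r0;
      const mat Ab = A.rows(a0, a0 + L - 1);
      const mat dH = dHc.submat(r0, v0, r1, v1);
      mat dA = dH * Va.submat(r0, v0, r1, v1).t();
      dVa.submat(r0, v0, r1, v1) = Ab.t() * dH;
      // softmax Jacobian: dS = A % (dA - rowSums(dA % A)), then 1/sqrt(d_k)
      dA.each_col() -= sum(dA % Ab, 1);
      const mat dS = Ab % dA / sc;
      dQa.submat(r0, q0, r1, q1) = dS * Ka.submat(r0, q0, r1, q1);
      dKa.submat(r0, q0, r1, q1) = dS.t() * Qa.submat(r0, q0, r1, q1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQa") = dQa,
                            Rcpp::Named("dKa") = dKa,
                            Rcpp::Named("dVa") = dVa);
}
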