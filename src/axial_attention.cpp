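// Gated axial attention core: slice-and-head loops over small dense
// matrices. The projections (q/k/v and their weight gradients) stay in R
// where they are single BLAS calls; this file only handles the per-slice
// attention arithmetic, which is allocation-bound in pure R.
//
// Layout: projected features arrive as C x (S*R) matrices whose column
// block r holds the S positions of slice r; head h occupies rows
// [h*d, (h+1)*d). Positional tables are S x S x n_heads cubes. Gates are
// (G_Q, G_K, G_V1, G_V2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List axattn_fwd_cpp(const arma::mat& Qm, const arma::mat& Km,
                          const arma::mat& Vm, const arma::cube& Rq,
                          const arma::cube& Rk, const arma::cube& Rv,
                          const arma::vec& gates, int d, int S, int R,
                          int nh, bool keep_attention) {
  const double gq = gates(0), gk = gates(1), gv1 = gates(2), gv2 = gates(3);
  mat Y(Qm.n_rows, Qm.n_cols, fill::zeros);
  // caches for the backward pass: softmax maps and positional value sums
  mat Abig(keep_attention ? S * S : 1, keep_attention ? R * nh : 1,
           fill::zeros);
  mat U(S, R * nh, fill::zeros);
  for (int r = 0; r < R; ++r) {
    const uword c0 = (uword)r * S;
    for (int h = 0; h < nh; ++h) {
      const uword r0 = (uword)h * d;
      mat Q = Qm.submat(r0, c0, r0 + d - 1, c0 + S - 1);
      mat K = Km.submat(r0, c0, r0 + d - 1, c0 + S - 1);
      mat V = Vm.submat(r0, c0, r0 + d - 1, c0 + S - 1);
      vec sq = sum(Q, 0).t();
      vec sk = sum(K, 0).t();
      mat L = Q.t() * K;
      L += gq * (Rq.slice(h).each_col() % sq);
      L += gk * (Rk.slice(h).each_row() % sk.t());
      vec m = max(L, 1);
      L.each_col() -= m;
      mat A = exp(L);
      vec den = sum(A, 1);
      A.each_col() /= den;
      vec u = sum(A % Rv.slice(h), 1);
      mat Yh = gv1 * (V * A.t());
      Yh.each_row() += gv2 * u.t();
      Y.submat(r0, c0, r0 + d - 1, c0 + S - 1) = Yh;
      if (keep_attention)
        Abig.col((uword)r * nh + h) = vectorise(A);
      U.col((uword)r * nh + h) = u;
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("A") = Abig,
                            Rcpp::Named("U") = U);
}

// [[Rcpp::export]]
Rcpp::List axattn_bwd_cpp(const arma::mat& dYm, const arma::mat& Qm,
                          const arma::mat& Km, const arma::mat& Vm,
                          const arma::cube& Rq, const arma::cube& Rk,
                          const arma::cube& Rv, const arma::vec& gates,
                          int d, int S, int R, int nh) {
  const double gq_g = gates(0), gk_g = gates(1), gv1 = gates(2),
               gv2 = gates(3);
  mat dQm(Qm.n_rows, Qm.n_cols, fill::zeros);
  mat dKm(Km.n_rows, Km.n_cols, fill::zeros);
  mat dVm(Vm.n_rows, Vm.n_cols, fill::zeros);
  cube dRq(S, S, nh, fill::zeros), dRk(S, S, nh, fill::zeros),
      dRv(S, S, nh, fill::zeros);
  double dG_Q = 0, dG_K = 0, dG_V1 = 0, dG_V2 = 0;
  for (int r = 0; r < R; ++r) {
    const uword c0 = (uword)r * S;
    for (int h = 0; h < nh; ++h) {
      const uword r0 = (uword)h * d;
      mat Q = Qm.submat(r0, c0, r0 + d - 1, c0 + S - 1);
      mat K = Km.submat(r0, c0, r0 + d - 1, c0 + S - 1);
      mat V = Vm.submat(r0, c0, r0 + d - 1, c0 + S - 1);
      mat dY = dYm.submat(r0, c0, r0 + d - 1, c0 + S - 1);
      vec sq = sum(Q, 0).t();
      vec sk = sum(K, 0).t();
      // recompute the softmax map (cheaper than shipping it from R)
      mat L = Q.t() * K;
      L += gq_g * (Rq.slice(h).each_col() % sq);
      L += gk_g * (Rk.slice(h).each_row() % sk.t());
      vec m = max(L, 1);
      L.each_col() -= m;
      mat A = exp(L);
      vec den = sum(A, 1);
      A.each_col() /= den;
      vec u = sum(A % Rv.slice(h), 1);

      vec c = sum(dY, 0).t();
      mat VA = V * A.t();
      dG_V1 += accu(dY % VA);
      dG_V2 += dot(c, u);
      mat dA = gv1 * (dY.t() * V);
      dA += gv2 * (Rv.slice(h).each_col() % c);
      dRv.slice(h) += gv2 * (A.each_col() % c);
      mat dV = gv1 * (dY * A);
      vec srow = sum(dA % A, 1);
      mat dL = A % (dA.each_col() - srow);
      mat dQ = K * dL.t();
      vec gqv = sum(dL % Rq.slice(h), 1);
      dQ.each_row() += gq_g * gqv.t();
      mat dK = Q * dL;
      vec gkv = sum(dL % Rk.slice(h), 0).t();
      dK.each_row() += gk_g * gkv.t();
      dRq.slice(h) += gq_g * (dL.each_col() % sq);
      dRk.slice(h) += gk_g * (dL.each_row() % sk.t());
      dG_Q += accu((Rq.slice(h).each_col() % sq) % dL);
      dG_K += accu((Rk.slice(h).each_row() % sk.t()) % dL);
      dQm.submat(r0, c0, r0 + d - 1, c0 + S - 1) = dQ;
      dKm.submat(r0, c0, r0 + d - 1, c0 + S - 1) = dK;
      dVm.submat(r0, c0, r0 + d - 1, c0 + S - 1) = dV;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("dQm") = dQm, Rcpp::Named("dKm") = dKm,
      Rcpp::Named("dVm") = dVm, Rcpp::Named("dRq") = dRq,
      Rcpp::Named("dRk") = dRk, Rcpp::Named("dRv") = dRv,
      Rcpp::Named("dgates") = vec({dG_Q, dG_K, dG_V1, dG_V2}));
}
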