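// Fused per-sample kernels for the attention module. Batches are stacked
// row-wise (block b of P rows at rows b*P..(b+1)*P-1). These kernels avoid
// materialising the (B*P x P) intermediates in R; the R level keeps the
// graph logic and caches only what the backward pass needs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static void softmax_rows_inplace(arma::mat& S) {
  S.each_col() -= arma::max(S, 1);
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
}

// one attention head: A = softmax(Qp Kp' / sqrt(dk)) row-wise, head = A Vp
// [[Rcpp::export]]
Rcpp::List attn_head_cpp(const arma::mat& Qp, const arma::mat& Kp,
                         const arma::mat& Vp, const int nb) {
  const arma::uword P = Qp.n_rows / nb;
  const arma::uword Pk = Kp.n_rows / nb;
  const double scale = 1.0 / std::sqrt((double)Qp.n_cols);
  arma::mat A(Qp.n_rows, Pk), head(Qp.n_rows, Vp.n_cols);
  for (int b = 0; b < nb; ++b) {
    const arma::uword q0 = b * P, q1 = (b + 1) * P - 1;
    const arma::uword k0 = b * Pk, k1 = (b + 1) * Pk - 1;
    arma::mat S = Qp.rows(q0, q1) * Kp.rows(k0, k1).t() * scale;
    softmax_rows_inplace(S);
    A.rows(q0, q1) = S;
    head.rows(q0, q1) = S * Vp.rows(k0, k1);
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("head") = head);
}

// backward of one head given its cached softmax weights
// [[Rcpp::export]]
Rcpp::List attn_head_bwd_cpp(const arma::mat& A, const arma::mat& Qp,
                             const arma::mat& Kp, const arma::mat& Vp,
                             const arma::mat& dhead, const int nb) {
  const arma::uword P = Qp.n_rows / nb;
  const arma::uword Pk = Kp.n_rows / nb;
  const double scale = 1.0 / std::sqrt((double)Qp.n_cols);
  arma::mat dQp(arma::size(Qp)), dKp(arma::size(Kp)), dVp(arma::size(Vp));
  for (int b = 0; b < nb; ++b) {
    const arma::uword q0 = b * P, q1 = (b + 1) * P - 1;
    const arma::uword k0 = b * Pk, k1 = (b + 1) * Pk - 1;
    const arma::mat Ab = A.rows(q0, q1);
    arma::mat dA = dhead.rows(q0, q1) * Vp.rows(k0, k1).t();
    // softmax Jacobian, row-wise: dS = A o (dA - rowsum(dA o A))
    arma::vec rs = arma::sum(dA % Ab, 1);
    arma::mat dS = Ab % (dA.each_col() - rs) * scale;
    dQp.rows(q0, q1) = dS * Kp.rows(k0, k1);
    dKp.rows(k0, k1) = dS.t() * Qp.rows(q0, q1);
    dVp.rows(k0, k1) = Ab.t() * dhead.rows(q0, q1);
  }
  return Rcpp::List::create(Rcpp::Named("dQp") = dQp,
                            Rcpp::Named("dKp") = dKp,
                            Rcpp::Named("dVp") = dVp);
}

// interaction map G = M Hq' with average/max pooling over its last axis;
// returns pooled vectors and the argmax needed by the backward pass
// [[Rcpp::export]]
Rcpp::List pool_map_cpp(const arma::mat& M, const arma::mat& Hq,
                        const int nb) {
  const arma::uword P = M.n_rows / nb;
  arma::vec avg(M.n_rows), mx(M.n_rows);
  arma::uvec amax(M.n_rows);
  for (int b = 0; b < nb; ++b) {
    const arma::uword r0 = b * P, r1 = (b + 1) * P - 1;
    arma::mat G = M.rows(r0, r1) * Hq.rows(r0, r1).t();
    for (arma::uword i = 0; i < P; ++i) {
      const arma::rowvec g = G.row(i);
      avg(r0 + i) = arma::mean(g);
      arma::uword j = g.index_max();
      amax(r0 + i) = j + 1;            // 1-based for R
      mx(r0 + i) = g(j);
    }
  }
  return Rcpp::List::create(Rcpp::Named("avg") = avg, Rcpp::Named("mx") = mx,
                            Rcpp::Named("amax") = amax);
}

// backward of the pooled interaction map
// [[Rcpp::export]]
Rcpp::List pool_map_bwd_cpp(const arma::mat& M, const arma::mat& Hq,
                            const arma::vec& davg, const arma::vec& dmx,
                            const arma::uvec& amax, const int nb) {
  const arma::uword P = M.n_rows / nb;
  arma::mat dM(arma::size(M)), dHq(arma::size(Hq));
  for (int b = 0; b < nb; ++b) {
    const arma::uword r0 = b * P, r1 = (b + 1) * P - 1;
    arma::mat dG(P, P);
    for (arma::uword i = 0; i < P; ++i) {
      dG.row(i).fill(davg(r0 + i) / (double)P);
      dG(i, amax(r0 + i) - 1) += dmx(r0 + i);
    }
    dM.rows(r0, r1) = dG * Hq.rows(r0, r1);
    dHq.rows(r0, r1) = dG.t() * M.rows(r0, r1);
  }
  return Rcpp::List::create(Rcpp::Named("dM") = dM, Rcpp::Named("dHq") = dHq);
}
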