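// Batched per-sample matrix multiplication for the attention module.
//
// A batch of B small matrices is stored stacked row-wise: A holds B blocks of
// ra rows each ((b,i) at row b*ra + i). bmm_cpp multiplies corresponding
// blocks of A and C under one of three transpose modes:
//   mode 0 ("nn"): out_b = A_b * C_b
//   mode 1 ("nt"): out_b = A_b * C_b^T
//   mode 2 ("tn"): out_b = A_b^T * C_b
// This is the only inner loop of the model hot enough to warrant compiled
// code; everything else is ordinary (already batched) matrix algebra in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export]]
arma::mat bmm_cpp(const arma::mat& A, const arma::mat& C, const int nb,
                  const int mode) {
  if (nb <= 0) Rcpp::stop("nb must be positive");
  if (A.n_rows % nb != 0 || C.n_rows % nb != 0)
    Rcpp::stop("row counts must be multiples of the batch size");
  const arma::uword ra = A.n_rows / nb;
  const arma::uword rc = C.n_rows / nb;

  arma::uword out_r, out_c;
  if (mode == 0) {        // A_b (ra x ca) * C_b (rc x cc), ca == rc
    if (A.n_cols != rc) Rcpp::stop("nn: ncol(A) must equal block rows of C");
    out_r = ra; out_c = C.n_cols;
  } else if (mode == 1) { // A_b * C_b^T, ca == cc
    if (A.n_cols != C.n_cols) Rcpp::stop("nt: ncol(A) must equal ncol(C)");
    out_r = ra; out_c = rc;
  } else if (mode == 2) { // A_b^T * C_b, ra == rc
    if (ra != rc) Rcpp::stop("tn: block rows of A and C must match");
    out_r = A.n_cols; out_c = C.n_cols;
  } else {
    Rcpp::stop("mode must be 0 (nn), 1 (nt) or 2 (tn)");
  }

  arma::mat out(out_r * nb, out_c);
  for (int b = 0; b < nb; ++b) {
    const auto Ab = A.rows(b * ra, (b + 1) * ra - 1);
    const auto Cb = C.rows(b * rc, (b + 1) * rc - 1);
    if (mode == 0)
      out.rows(b * out_r, (b + 1) * out_r - 1) = Ab * Cb;
    else if (mode == 1)
      out.rows(b * out_r, (b + 1) * out_r - 1) = Ab * Cb.t();
    else
      out.rows(b * out_r, (b + 1) * out_r - 1) = Ab.t() * Cb;
  }
  return out;
}
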