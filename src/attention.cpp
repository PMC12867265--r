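// Batched scaled-dot-product self-attention kernels.
//
// Seq tensors arrive as (B*L) x C matrices, rows sample-major. Per head the
// kernels work on dh x (B*L) transposes so each sample's block is a
// contiguous column range and every small GEMM is copy-free. The attention
// weights are kept key-major: A(j, i) is the weight of key j for query i, so
// the softmax runs down contiguous columns. They are returned as an
// (L*H) x (B*L) matrix and handed back verbatim to the backward kernel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void softmax_cols(mat& S) {
  const uword L = S.n_rows;
  for (uword i = 0; i < S.n_cols; ++i) {
    double* col = S.colptr(i);
    double mx = col[0];
    for (uword j = 1; j < L; ++j) if (col[j] > mx) mx = col[j];
    double sum = 0.0;
    for (uword j = 0; j < L; ++j) { col[j] = std::exp(col[j] - mx); sum += col[j]; }
    const double inv = 1.0 / sum;
    for (uword j = 0; j < L; ++j) col[j] *= inv;
  }
}

// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                            const arma::mat& V, const int B, const int L,
                            const int H) {
  const int C = Q.n_cols;
  const int dh = C / H;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat ctx(Q.n_rows, C);
  mat Aout((size_t) L * H, Q.n_rows);
  mat ctx_t(dh, Q.n_rows);
  mat S(L, L);
  for (int h = 0; h < H; ++h) {
    const int c0 = h * dh, c1 = h * dh + dh - 1;
    const mat Qt = Q.cols(c0, c1).t();
    const mat Kt = K.cols(c0, c1).t();
    const mat Vt = V.cols(c0, c1).t();
    for (int b = 0; b < B; ++b) {
      const int r0 = b * L, r1 = b * L + L - 1;
      S = Kt.cols(r0, r1).t() * Qt.cols(r0, r1);
      S *= scale;
      softmax_cols(S);
      ctx_t.cols(r0, r1) = Vt.cols(r0, r1) * S;
      Aout.submat(h * L, r0, h * L + L - 1, r1) = S;
    }
    ctx.cols(c0, c1) = ctx_t.t();
  }
  return Rcpp::List::create(Rcpp::Named("ctx") = ctx,
                            Rcpp::Named("A") = Aout);
}

// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::mat& Q, const arma::mat& K,
                             const arma::mat& V, const arma::mat& A,
                             const arma::mat& dctx, const int B, const int L,
                             const int H) {
  const int C = Q.n_cols;
  const int dh = C / H;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat dQ(Q.n_rows, C), dK(Q.n_rows, C), dV(Q.n_rows, C);
  mat dQt(dh, Q.n_rows), dKt(dh, Q.n_rows), dVt(dh, Q.n_rows);
  mat dA(L, L), dS(L, L), Ab(L, L);
  for (int h = 0; h < H; ++h) {
    const int c0 = h * dh, c1 = h * dh + dh - 1;
    const mat Qt = Q.cols(c0, c1).t();
    const mat Kt = K.cols(c0, c1).t();
    const mat Vt = V.cols(c0, c1).t();
    const mat dCt = dctx.cols(c0, c1).t();
    for (int b = 0; b < B; ++b) {
      const int r0 = b * L, r1 = b * L + L - 1;
      Ab = A.submat(h * L, r0, h * L + L - 1, r1);
      dA = Vt.cols(r0, r1).t() * dCt.cols(r0, r1);
      dVt.cols(r0, r1) = dCt.cols(r0, r1) * Ab.t();
      // softmax backward down each (contiguous) query column
      for (int i = 0; i < L; ++i) {
        const double* a = Ab.colptr(i);
        double* da = dA.colptr(i);
        double* ds = dS.colptr(i);
        double dot = 0.0;
        for (int j = 0; j < L; ++j) dot += da[j] * a[j];
        for (int j = 0; j < L; ++j) ds[j] = a[j] * (da[j] - dot) * scale;
      }
      dQt.cols(r0, r1) = Kt.cols(r0, r1) * dS;
      dKt.cols(r0, r1) = Qt.cols(r0, r1) * dS.t();
    }
    dQ.cols(c0, c1) = dQt.t();
    dK.cols(c0, c1) = dKt.t();
    dV.cols(c0, c1) = dVt.t();
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
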