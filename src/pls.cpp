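// NIPALS PLS2 core. Per component the NIPALS fixed point (w ~ X'Yq,
// q ~ Y'Xw) is obtained by power iteration on the K x K matrix (S'S with
// S = X'Y), followed by score/loading extraction and X-deflation. The
// leave-one-out driver refits the decomposition for every held-out row so
// cross-validation has no R-level loop overhead.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct PlsFit {
  vec x_mean, y_mean, tss;
  mat W, P, Q, T;
};

static PlsFit pls2_core(const mat& X, const mat& Y, const int A,
                        const double tol, const int max_iter) {
  const uword n = X.n_rows, p = X.n_cols, K = Y.n_cols;
  PlsFit f;
  f.x_mean = mean(X, 0).t();
  f.y_mean = mean(Y, 0).t();
  mat Xd = X.each_row() - f.x_mean.t();
  mat Yc = Y.each_row() - f.y_mean.t();
  if (accu(square(Yc)) == 0.0)
    throw Rcpp::exception("Y has zero variance in every column");
  f.W.zeros(p, A); f.P.zeros(p, A); f.Q.zeros(K, A);
  f.T.zeros(n, A); f.tss.zeros(A);
  const double x_norm0 = std::max(norm(Xd, "fro"), 1.0);
  for (int a = 0; a < A; ++a) {
    mat S = Xd.t() * Yc;                       // p x K
    vec w;
    if (K == 1) {
      w = S.col(0);
    } else {
      mat M = S.t() * S;                       // K x K
      vec q(K, fill::zeros);
      q(M.diag().index_max()) = 1.0;
      for (int it = 0; it < max_iter; ++it) {
        vec q_new = M * q;
        double nq = norm(q_new);
        if (nq == 0.0) break;
        q_new /= nq;
        double delta = norm(q_new - q);
        q = q_new;
        if (delta < tol) break;
      }
      w = S * q;
    }
    double nw = norm(w);
    if (nw < 1e-12 * x_norm0)
      throw Rcpp::exception(("component " + std::to_string(a + 1) +
        ": X is exhausted (effective rank < n_components)").c_str());
    w /= nw;
    if (w(index_max(abs(w))) < 0) w = -w;      // deterministic sign
    vec t = Xd * w;
    double tt = dot(t, t);
    if (tt < 1e-24 * x_norm0 * x_norm0)
      throw Rcpp::exception(("component " + std::to_string(a + 1) +
        ": degenerate score vector (rank exhausted)").c_str());
    vec pv = Xd.t() * t / tt;
    vec qv = Yc.t() * t / tt;
    Xd -= t * pv.t();
    f.W.col(a) = w; f.P.col(a) = pv; f.Q.col(a) = qv;
    f.T.col(a) = t; f.tss(a) = tt;
  }
  return f;
}

// [[Rcpp::export]]
Rcpp::List cpp_pls2_fit(const arma::mat& X, const arma::mat& Y, const int A,
                        const double tol, const int max_iter) {
  PlsFit f = pls2_core(X, Y, A, tol, max_iter);
  return Rcpp::List::create(
    Rcpp::Named("x_mean") = f.x_mean, Rcpp::Named("y_mean") = f.y_mean,
    Rcpp::Named("weights") = f.W, Rcpp::Named("x_scores") = f.T,
    Rcpp::Named("x_loadings") = f.P, Rcpp::Named("y_loadings") = f.Q,
    Rcpp::Named("score_ssq") = f.tss);
}

// Held-out predictions: row i of the result is the PLS2 prediction for
// sample i from the model refitted (and re-centered) without it. With
// all_components = true the result is n x (K*A), blocks of K columns per
// component count a = 1..A; otherwise n x K at a = A.
// [[Rcpp::export]]
arma::mat cpp_loo_predict(const arma::mat& X, const arma::mat& Y, const int A,
                          const double tol, const int max_iter,
                          const bool all_components) {
  const uword n = X.n_rows, K = Y.n_cols;
  mat out(n, all_components ? K * (uword)A : K);
  uvec all = regspace<uvec>(0, n - 1);
  for (uword i = 0; i < n; ++i) {
    uvec keep = all.elem(find(all != i));
    PlsFit f = pls2_core(X.rows(keep), Y.rows(keep), A, tol, max_iter);
    vec xc = X.row(i).t() - f.x_mean;
    if (all_components) {
      for (int a = 1; a <= A; ++a) {
        mat Wa = f.W.cols(0, a - 1), Pa = f.P.cols(0, a - 1),
            Qa = f.Q.cols(0, a - 1);
        mat B = Wa * solve(Pa.t() * Wa, Qa.t());
        out(span(i), span((a - 1) * K, a * K - 1)) =
          (B.t() * xc + f.y_mean).t();
      }
    } else {
      mat B = f.W * solve(f.P.t() * f.W, f.Q.t());
      out.row(i) = (B.t() * xc + f.y_mean).t();
    }
  }
  return out;
}
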