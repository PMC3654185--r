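// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
using namespace Rcpp;

// Gaussian variance-components likelihoods with fixed effects profiled
// out by GLS.  Families are passed in GROUPS: all families in a group
// share the same covariance structure (X, Pi, K) and differ only in
// their trait vectors, which arrive as the columns of Y.  One Cholesky
// then serves the whole group, which is what makes the model-based
// simulation worlds (a handful of distinct IBD patterns repeated over
// hundreds of sibships) cheap.  Per family the covariance is
//   Omega = s2_q * Pi + s2_g * K + s2_e * I   (K = 2 * kinship);
// the bivariate version stacks two traits with cross-blocks
//   r_q s_q1 s_q2 Pi + r_g s_g1 s_g2 K + r_e s_e1 s_e2 * (same person).

static bool safe_chol(arma::mat &L, const arma::mat &A) {
  if (arma::chol(L, A, "lower")) return true;
  arma::mat Aj = A + 1e-8 * arma::eye(A.n_rows, A.n_cols);
  return arma::chol(L, Aj, "lower");
}

// groups: list of list(X [n x p], Pi, K [n x n], Y [n x m])
// [[Rcpp::export]]
List vc_loglik_uni_cpp(NumericVector sig, List groups) {
  const double sq = sig[0], sg = sig[1], se = sig[2];
  const int ng = groups.size();
  int p = as<arma::mat>(as<List>(groups[0])["X"]).n_cols;
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  double logdet = 0.0, yOy = 0.0;
  long N = 0;
  std::vector<arma::mat> OiY(ng), Xg(ng), OiX(ng);
  for (int g = 0; g < ng; ++g) {
    List gg = groups[g];
    arma::mat X = as<arma::mat>(gg["X"]);
    arma::mat Pi = as<arma::mat>(gg["Pi"]);
    arma::mat K = as<arma::mat>(gg["K"]);
    arma::mat Y = as<arma::mat>(gg["Y"]);
    const int n = Y.n_rows, m = Y.n_cols;
    arma::mat Om = sq * Pi + sg * K + se * arma::eye(n, n);
    arma::mat L;
    if (!safe_chol(L, Om))
      return List::create(_["loglik"] = R_NegInf, _["beta"] = R_NilValue);
    arma::mat Li = arma::inv(arma::trimatl(L));
    arma::mat Oi = Li.t() * Li;
    OiX[g] = Oi * X;
    OiY[g] = Oi * Y;
    Xg[g] = X;
    logdet += m * 2.0 * arma::accu(arma::log(L.diag()));
    A += m * (X.t() * OiX[g]);
    b += X.t() * (OiY[g] * arma::ones(m));
    yOy += arma::accu(Y % OiY[g]);
    N += (long)n * m;
  }
  arma::vec beta;
  if (!arma::solve(beta, A, b, arma::solve_opts::likely_sympd))
    return List::create(_["loglik"] = R_NegInf, _["beta"] = R_NilValue);
  const double quad = yOy - 2.0 * arma::dot(beta, b) + arma::dot(beta, A * beta);
  const double ll = -0.5 * (logdet + quad + N * std::log(2.0 * M_PI));
  return List::create(_["loglik"] = ll, _["beta"] = beta);
}

// par = (sq1, sg1, se1, sq2, sg2, se2, rq, rg, re)
// groups: list(Pi, K [members x members], idx1, idx2 (1-based),
//              X1 [n1 x p1], X2 [n2 x p2], Y1 [n1 x m], Y2 [n2 x m])
// [[Rcpp::export]]
List vc_loglik_biv_cpp(NumericVector par, List groups) {
  const double sq1 = par[0], sg1 = par[1], se1 = par[2];
  const double sq2 = par[3], sg2 = par[4], se2 = par[5];
  const double rq = par[6], rg = par[7], re = par[8];
  const double cq = rq * std::sqrt(sq1 * sq2);
  const double cg = rg * std::sqrt(sg1 * sg2);
  const double ce = re * std::sqrt(se1 * se2);
  const int ng = groups.size();
  List g0 = groups[0];
  const int p1 = as<arma::mat>(g0["X1"]).n_cols;
  const int p2 = as<arma::mat>(g0["X2"]).n_cols;
  const int p = p1 + p2;
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  double logdet = 0.0, yOy = 0.0;
  long N = 0;
  for (int g = 0; g < ng; ++g) {
    List gg = groups[g];
    arma::mat Pi = as<arma::mat>(gg["Pi"]);
    arma::mat K = as<arma::mat>(gg["K"]);
    arma::uvec i1 = as<arma::uvec>(gg["idx1"]) - 1;
    arma::uvec i2 = as<arma::uvec>(gg["idx2"]) - 1;
    arma::mat X1 = as<arma::mat>(gg["X1"]);
    arma::mat X2 = as<arma::mat>(gg["X2"]);
    arma::mat Y1 = as<arma::mat>(gg["Y1"]);
    arma::mat Y2 = as<arma::mat>(gg["Y2"]);
    const int n1 = i1.n_elem, n2 = i2.n_elem, n = n1 + n2;
    const int m = std::max(Y1.n_cols, Y2.n_cols);
    if (n == 0) continue;
    arma::mat Om(n, n, arma::fill::zeros);
    if (n1 > 0)
      Om.submat(0, 0, n1 - 1, n1 - 1) =
          sq1 * Pi.submat(i1, i1) + sg1 * K.submat(i1, i1) + se1 * arma::eye(n1, n1);
    if (n2 > 0)
      Om.submat(n1, n1, n - 1, n - 1) =
          sq2 * Pi.submat(i2, i2) + sg2 * K.submat(i2, i2) + se2 * arma::eye(n2, n2);
    if (n1 > 0 && n2 > 0) {
      arma::mat same(n1, n2, arma::fill::zeros);
      for (int a = 0; a < n1; ++a)
        for (int c = 0; c < n2; ++c)
          if (i1[a] == i2[c]) same(a, c) = 1.0;
      arma::mat C = cq * Pi.submat(i1, i2) + cg * K.submat(i1, i2) + ce * same;
      Om.submat(0, n1, n1 - 1, n - 1) = C;
      Om.submat(n1, 0, n - 1, n1 - 1) = C.t();
    }
    arma::mat Y(n, m, arma::fill::zeros);
    if (n1 > 0) Y.rows(0, n1 - 1) = Y1;
    if (n2 > 0) Y.rows(n1, n - 1) = Y2;
    arma::mat X(n, p, arma::fill::zeros);
    if (n1 > 0) X.submat(0, 0, n1 - 1, p1 - 1) = X1;
    if (n2 > 0) X.submat(n1, p1, n - 1, p - 1) = X2;
    arma::mat L;
    if (!safe_chol(L, Om))
      return List::create(_["loglik"] = R_NegInf, _["beta"] = R_NilValue);
    arma::mat Li = arma::inv(arma::trimatl(L));
    arma::mat Oi = Li.t() * Li;
    arma::mat OiX = Oi * X;
    arma::mat OiY = Oi * Y;
    logdet += m * 2.0 * arma::accu(arma::log(L.diag()));
    A += m * (X.t() * OiX);
    b += X.t() * (OiY * arma::ones(m));
    yOy += arma::accu(Y % OiY);
    N += (long)n * m;
  }
  arma::vec beta;
  if (!arma::solve(beta, A, b, arma::solve_opts::likely_sympd))
    return List::create(_["loglik"] = R_NegInf, _["beta"] = R_NilValue);
  const double quad = yOy - 2.0 * arma::dot(beta, b) + arma::dot(beta, A * beta);
  const double ll = -0.5 * (logdet + quad + N * std::log(2.0 * M_PI));
  return List::create(_["loglik"] = ll, _["beta"] = beta);
}
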